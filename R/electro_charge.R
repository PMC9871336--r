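#' @name electro_charge
#' @title Peptide net charge and buffer electrostatics
#'
#' @description
#' Sequence-level charge bookkeeping for loop and coiled-coil segments
#' (integer per-residue charges at pH 6.9: K/R +1, D/E -1, histidine neutral,
#' termini ignored), the packaged loop-12 charge ledger for the KIF1A
#' construct series, generic ionic-strength arithmetic, and the Debye
#' screening length that sets how far K-loop/E-hook electrostatics reach in a
#' given buffer.
NULL

#' Integer per-residue charge model
#'
#' Default charges reflect pH 6.9: lysine and arginine +1, aspartate and
#' glutamate -1, histidine 0 (pKa ~6, mostly neutral), all other residues 0.
#' Termini are ignored because the segments of interest are internal loops
#' and coiled coils, not free peptides.
#'
#' @param residue_charge named integer vector of residue charges overriding
#'   the defaults; values must lie in -1..1.
#' @param ph_label label recording the pH the charges assume.
#' @return object of class `charge_model`.
#' @export
charge_model <- function(residue_charge = NULL, ph_label = "6.9") {
  charges <- c(K = 1L, R = 1L, D = -1L, E = -1L, H = 0L)
  if (!is.null(residue_charge)) {
    if (is.null(names(residue_charge)) ||
        any(abs(residue_charge) > 1) ||
        any(residue_charge != as.integer(residue_charge))) {
      kr_stop("`residue_charge` must be a named vector of integers in -1..1",
              "kinrace_validation_error")
    }
    charges[names(residue_charge)] <- as.integer(residue_charge)
  }
  structure(list(residue_charge = charges, ph_label = ph_label),
            class = "charge_model")
}

.aa_codes <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Net charge and lysine count of a peptide segment
#'
#' @param sequence one-letter amino-acid string (standard 20 codes).
#' @param model a [charge_model()] (default: pH 6.9 integer charges).
#' @return list with `net_charge` (integer) and `lysine_count` (integer).
#' @examples
#' peptide_net_charge("KKKKKK")  # +6, 6 lysines
#' peptide_net_charge("QQQQ")    # 0: glutamine is uncharged at pH 6.9
#' @export
peptide_net_charge <- function(sequence, model = charge_model()) {
  stopifnot(inherits(model, "charge_model"))
  if (!is.character(sequence) || length(sequence) != 1) {
    kr_stop("`sequence` must be a single string", "kinrace_validation_error")
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(res %in% .aa_codes))
  if (length(bad) > 0) {
    kr_stop(sprintf("unknown residue code '%s' at position %d",
                    res[bad[1]], bad[1]), "kinrace_validation_error")
  }
  ch <- model$residue_charge[res]
  ch[is.na(ch)] <- 0L
  list(net_charge = as.integer(sum(ch)),
       lysine_count = as.integer(sum(res == "K")))
}

#' Read peptide sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector of sequences.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) {
    kr_stop(sprintf("file not found: %s", path), "kinrace_validation_error")
  }
  aas <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aas), names(aas))
}

#' Packaged loop-12 charge ledger
#'
#' Lysine count and net charge of the loop-12 (K-loop) domain for the KIF1A
#' construct series: WT (+4), SuperK (+7, three neutral residues replaced by
#' lysines), the kinesin-1 loop swap K1L12 (+1), and the glutamine
#' substitution mutants 4Q (0) and 5Q (-1). The
#' `k_substitutions_vs_wt` column records the signed lysine change relative
#' to WT for substitution mutants (`NA` for the loop swap, whose sequence is
#' unrelated).
#'
#' @return data frame with columns `construct`, `lysine_count`, `net_charge`,
#'   `k_substitutions_vs_wt`.
#' @export
kloop_ledger <- function() {
  path <- system.file("extdata", "kloop_ledger.json", package = "kinrace")
  raw <- jsonlite::fromJSON(path)
  df <- raw$entries
  df$k_substitutions_vs_wt <- vapply(df$k_substitutions_vs_wt, function(v) {
    if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  attr(df, "wt_construct") <- raw$wt_construct
  df
}

#' Validate a loop-12 charge ledger
#'
#' Checks internal consistency of the ledger: for substitution mutants, the
#' net-charge change relative to WT must equal the signed number of lysine
#' substitutions (each K added is +1, each K replaced by a neutral residue is
#' -1), and the lysine-count change must match. When sequences are supplied
#' (named by construct), the net charge and lysine count are recomputed from
#' sequence and compared. Mismatches are itemized in the returned report, not
#' raised as errors.
#'
#' @param entries ledger data frame as returned by [kloop_ledger()].
#' @param sequences optional named character vector of loop-12 sequences.
#' @param model a [charge_model()] used for sequence recomputation.
#' @return data frame with one row per check: `construct`, `check`, `ok`,
#'   `detail`.
#' @export
validate_charge_ledger <- function(entries, sequences = NULL,
                                   model = charge_model()) {
  if (is.null(entries) || nrow(entries) == 0) {
    kr_stop("`entries` must be nonempty", "kinrace_validation_error")
  }
  wt_name <- attr(entries, "wt_construct")
  if (is.null(wt_name)) wt_name <- entries$construct[1]
  wt <- entries[entries$construct == wt_name, ]
  rows <- list()
  add <- function(construct, check, ok, detail) {
    rows[[length(rows) + 1]] <<- data.frame(
      construct = construct, check = check, ok = ok, detail = detail,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    subs <- e$k_substitutions_vs_wt
    if (!is.na(subs) && nrow(wt) == 1) {
      d_charge <- e$net_charge - wt$net_charge
      d_lys <- e$lysine_count - wt$lysine_count
      add(e$construct, "substitution_charge_delta", d_charge == subs,
          sprintf("charge delta %+d vs %+d K substitutions", d_charge, subs))
      add(e$construct, "substitution_lysine_delta", d_lys == subs,
          sprintf("lysine delta %+d vs %+d K substitutions", d_lys, subs))
    }
    if (!is.null(sequences) && e$construct %in% names(sequences)) {
      comp <- peptide_net_charge(sequences[[e$construct]], model)
      add(e$construct, "sequence_net_charge",
          comp$net_charge == e$net_charge,
          sprintf("sequence gives %+d, ledger says %+d",
                  comp$net_charge, e$net_charge))
      add(e$construct, "sequence_lysine_count",
          comp$lysine_count == e$lysine_count,
          sprintf("sequence gives %d, ledger says %d",
                  comp$lysine_count, e$lysine_count))
    }
  }
  do.call(rbind, rows)
}

#' Ionic strength of a species list
#'
#' `I = 1/2 * sum(c_i * z_i^2)`. Buffer speciation (which ionic species a
#' buffer mix actually contains at a given pH) is the caller's input; this is
#' the generic arithmetic only.
#'
#' @param concentrations_mM species concentrations in mM (>= 0).
#' @param charges integer charges z of each species.
#' @return ionic strength in mM.
#' @examples
#' ionic_strength(c(100, 100), c(1, -1))  # 100 mM
#' ionic_strength(c(1, 2), c(2, -1))      # 3 mM
#' @export
ionic_strength <- function(concentrations_mM, charges) {
  if (length(concentrations_mM) != length(charges)) {
    kr_stop("concentrations and charges must match in length",
            "kinrace_validation_error")
  }
  if (any(concentrations_mM < 0)) {
    kr_stop("concentrations must be nonnegative", "kinrace_domain_error")
  }
  if (length(concentrations_mM) == 0) return(0)
  0.5 * sum(concentrations_mM * charges^2)
}

#' Debye screening length of an electrolyte
#'
#' `lambda_D = sqrt(eps0 * eps_r * kB * T / (2 * NA * e^2 * I))`, returned in
#' nm; at 298.15 K in water (eps_r = 78.5) this is approximately
#' `0.304 / sqrt(I[M])` nm. CODATA values are used for the physical
#' constants.
#'
#' @param ionic_strength_M ionic strength in mol/L (> 0).
#' @param temperature_K temperature in K (default 298.15).
#' @param relative_permittivity relative permittivity (default 78.5, water at
#'   25 C).
#' @return Debye length in nm.
#' @examples
#' debye_length(0.184)  # ~0.71 nm (BRB80)
#' debye_length(0.036)  # ~1.60 nm (BRB12)
#' @export
debye_length <- function(ionic_strength_M, temperature_K = 298.15,
                         relative_permittivity = 78.5) {
  if (!is.numeric(ionic_strength_M) || any(ionic_strength_M <= 0)) {
    kr_stop("ionic strength must be positive", "kinrace_domain_error")
  }
  e <- 1.602176634e-19        # C
  kB <- 1.380649e-23          # J/K
  NA_ <- 6.02214076e23        # 1/mol
  eps0 <- 8.8541878128e-12    # F/m
  I_m3 <- ionic_strength_M * 1000  # mol/m^3
  lambda_m <- sqrt(eps0 * relative_permittivity * kB * temperature_K /
                     (2 * NA_ * e^2 * I_m3))
  lambda_m * 1e9
}

#' Microtubule buffer presets
#'
#' The two PIPES buffers of the motility experiments with their printed
#' ionic strengths (at pH 6.9 with 1 mM MgCl2, 1 mM EGTA, 2 mM MgATP):
#' BRB80 (80 mM PIPES, I = 184 mM, near-physiological screening) and BRB12
#' (12 mM PIPES, I = 36 mM, enhanced electrostatics). The stored ionic
#' strengths are constants from a dedicated speciation calculation, not
#' recomputed here; [ionic_strength()] is available for user species lists.
#'
#' @return named list of `buffer_spec` objects with fields `name`,
#'   `pipes_mM`, `ionic_strength_mM`, `temperature_K`,
#'   `relative_permittivity`, `note`.
#' @examples
#' debye_length(buffer_presets()$BRB80$ionic_strength_mM / 1000)  # ~0.7 nm
#' @export
buffer_presets <- function() {
  spec <- function(name, pipes, I) {
    structure(list(name = name, pipes_mM = pipes, ionic_strength_mM = I,
                   temperature_K = 298.15, relative_permittivity = 78.5,
                   note = "ionic strength is a stored constant (pH 6.9; includes 1 mM MgCl2, 1 mM EGTA, 2 mM MgATP)"),
              class = "buffer_spec")
  }
  list(BRB80 = spec("BRB80", 80, 184), BRB12 = spec("BRB12", 12, 36))
}
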