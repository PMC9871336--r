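#' @name race_model
#' @title The kinetic race that sets kinesin processivity
#'
#' @description
#' During each stepping cycle a kinesin dimer passes through a vulnerable
#' one-head-bound state that resolves in one of two ways: the tethered head
#' attaches to the next tubulin site (rate `k_on_TH`, completing a step) or
#' the bound head detaches from the microtubule (rate `k_detach`, ending the
#' run). The per-cycle detachment probability is therefore
#' `p = k_detach / (k_on_TH + k_detach)`, the expected number of steps per run
#' is `1/p`, and, inverting, the tethered-head attachment rate can be
#' estimated from the measured off-rate in the weak-binding ADP state and the
#' run length expressed in 8-nm steps:
#' `k_on_TH = k_off * RL_steps`. These functions implement that algebra with
#' 95% CIs propagated by relative-error quadrature.
NULL

#' Per-cycle detachment probability of the kinetic race
#'
#' @param k_detach detachment rate from the one-head-bound state (s^-1),
#'   numeric scalar >= 0.
#' @param k_on_TH tethered-head attachment rate (s^-1), numeric scalar >= 0.
#' @param approximate if `TRUE`, use the weak-detachment approximation
#'   `k_detach / k_on_TH` instead of the exact `k_detach / (k_on_TH + k_detach)`.
#' @return detachment probability (dimensionless; the exact form is in
#'   \[0, 1\]).
#' @examples
#' detach_probability(0.56, 208)               # ~0.00268
#' detach_probability(0.56, 208, approximate = TRUE)
#' @export
detach_probability <- function(k_detach, k_on_TH, approximate = FALSE) {
  if (k_detach < 0 || k_on_TH < 0) {
    kr_stop("rates must be nonnegative", "kinrace_domain_error")
  }
  if (k_detach == 0 && k_on_TH == 0) {
    kr_stop("both rates zero: the race is undefined", "kinrace_race_error")
  }
  if (approximate) {
    if (k_on_TH == 0) {
      kr_stop("approximate form requires k_on_TH > 0", "kinrace_domain_error")
    }
    return(k_detach / k_on_TH)
  }
  k_detach / (k_on_TH + k_detach)
}

#' Expected run length in steps from a detachment probability
#'
#' @param p_detach per-cycle detachment probability, in (0, 1].
#' @return expected number of steps per run, `1 / p_detach`.
#' @export
run_length_in_steps_from_p <- function(p_detach) {
  if (!is.numeric(p_detach) || length(p_detach) != 1 || is.na(p_detach) ||
      p_detach <= 0 || p_detach > 1) {
    kr_stop("`p_detach` must lie in (0, 1]", "kinrace_domain_error")
  }
  1 / p_detach
}

#' Convert a run length to a step count
#'
#' @param run_length a positive `rate_estimate` in micrometers (bare scalars
#'   are accepted and treated as exact).
#' @param step_size step size in nm; 8 nm for kinesins walking on tubulin
#'   dimers.
#' @return dimensionless `rate_estimate` (steps), CI scaled by the same
#'   factor.
#' @examples
#' steps_from_run_length(rate_estimate(3.0, 0.02, "micrometer"))  # 375 +/- 2.5
#' @export
steps_from_run_length <- function(run_length, step_size = 8) {
  if (is.numeric(run_length)) {
    run_length <- rate_estimate(run_length, 0, "micrometer")
  }
  stopifnot(inherits(run_length, "rate_estimate"))
  if (run_length$unit != "micrometer") {
    kr_stop("`run_length` must carry unit micrometer", "kinrace_unit_error")
  }
  if (run_length$value <= 0 || step_size <= 0) {
    kr_stop("run length and step size must be positive",
            "kinrace_domain_error")
  }
  factor <- 1000 / step_size  # um -> nm, then per step
  rate_estimate(run_length$value * factor, run_length$ci95 * factor,
                "dimensionless")
}

#' Off-rate from a mean dwell time
#'
#' The off-rate is the reciprocal of the exponential dwell-time constant; the
#' relative CI is preserved.
#'
#' @param dwell a positive `rate_estimate` in seconds (bare scalars accepted).
#' @return `rate_estimate` in s^-1.
#' @examples
#' off_rate_from_dwell(rate_estimate(1.8, 0.08, "second"))  # 0.56 +/- 0.02
#' @export
off_rate_from_dwell <- function(dwell) {
  if (is.numeric(dwell)) dwell <- rate_estimate(dwell, 0, "second")
  stopifnot(inherits(dwell, "rate_estimate"))
  if (dwell$unit != "second") {
    kr_stop("`dwell` must carry unit second", "kinrace_unit_error")
  }
  if (dwell$value <= 0) {
    kr_stop("dwell time must be positive", "kinrace_domain_error")
  }
  re_reciprocal(dwell)
}

#' Tethered-head attachment rate from off-rate and run length in steps
#'
#' Inverts the kinetic race: with detachment probability approximately
#' `k_off / k_on_TH` and run length `1/p` steps,
#' `k_on_TH = k_off * RL_steps`.
#'
#' @param off_rate positive `rate_estimate` in s^-1.
#' @param steps positive dimensionless `rate_estimate` (run length in steps).
#' @return `rate_estimate` in s^-1; CI by relative-error quadrature.
#' @export
tethered_head_on_rate <- function(off_rate, steps) {
  stopifnot(inherits(off_rate, "rate_estimate"),
            inherits(steps, "rate_estimate"))
  if (off_rate$unit != "per_second" || steps$unit != "dimensionless") {
    kr_stop("expected off_rate in per_second and steps dimensionless",
            "kinrace_unit_error")
  }
  if (off_rate$value <= 0 || steps$value <= 0) {
    kr_stop("off-rate and steps must be positive", "kinrace_domain_error")
  }
  re_multiply(off_rate, steps)
}

#' Detachment rate from an affinity decomposition
#'
#' The dissociation constant for microtubule binding factors as
#' `K_D = k_detach / k_on_Mt`; given a pelleting-assay `K_D` and a
#' stopped-flow bimolecular on-rate, the detachment rate is their product.
#'
#' @param K_D positive `rate_estimate` in micromolar.
#' @param k_on_Mt positive `rate_estimate` in uM^-1 s^-1.
#' @return `rate_estimate` in s^-1.
#' @examples
#' detach_rate_from_affinity(rate_estimate(1.7, 1.0, "micromolar"),
#'                           rate_estimate(10.6, 0.5, "per_micromolar_per_second"))
#' @export
detach_rate_from_affinity <- function(K_D, k_on_Mt) {
  stopifnot(inherits(K_D, "rate_estimate"), inherits(k_on_Mt, "rate_estimate"))
  if (K_D$unit != "micromolar" || k_on_Mt$unit != "per_micromolar_per_second") {
    kr_stop("expected K_D in micromolar and k_on_Mt in per_micromolar_per_second",
            "kinrace_unit_error")
  }
  if (K_D$value <= 0 || k_on_Mt$value <= 0) {
    kr_stop("K_D and k_on_Mt must be positive", "kinrace_domain_error")
  }
  re_multiply(K_D, k_on_Mt)
}

#' Overall stepping rate from velocity
#'
#' @param velocity velocity in um/s, >= 0.
#' @param step_size step size in nm (> 0).
#' @return stepping rate in s^-1 (`velocity` in nm/s divided by `step_size`).
#' @examples
#' stepping_rate_from_velocity(1.7)  # 212.5 s^-1
#' @export
stepping_rate_from_velocity <- function(velocity, step_size = 8) {
  if (!is.numeric(velocity) || velocity < 0) {
    kr_stop("`velocity` must be nonnegative", "kinrace_domain_error")
  }
  if (step_size <= 0) {
    kr_stop("`step_size` must be positive", "kinrace_domain_error")
  }
  velocity * 1000 / step_size
}

#' Fold change between two like-unit estimates
#'
#' @param a,b `rate_estimate` objects with matching units; `b$value > 0`.
#' @return dimensionless `rate_estimate` `a / b` with quadrature CI.
#' @export
fold_change <- function(a, b) {
  stopifnot(inherits(a, "rate_estimate"), inherits(b, "rate_estimate"))
  if (a$unit != b$unit) {
    kr_stop(sprintf("unit mismatch in fold change: %s vs %s", a$unit, b$unit),
            "kinrace_unit_error")
  }
  if (b$value <= 0) {
    kr_stop("denominator must be positive", "kinrace_domain_error")
  }
  re_divide(a, b)
}

#' Kinetic-race table: from dwell times and run lengths to attachment rates
#'
#' For each construct row, computes the ADP off-rate (reciprocal dwell), the
#' run length in steps (run length / step size), and the tethered-head
#' attachment rate (off-rate times steps), all with 95% CIs propagated by
#' relative-error quadrature. Invalid rows (nonpositive or missing dwell or
#' run length) are flagged in the `error` column and processing continues.
#'
#' @param rows data frame with columns `construct`, `dwell_s`, `dwell_ci`,
#'   `run_length_um`, `run_length_ci`.
#' @param step_size step size in nm (default 8).
#' @return data frame with the input columns plus `off_rate_s`, `off_rate_ci`,
#'   `steps`, `steps_ci`, `kon_th_s`, `kon_th_ci`, `error`; input row order is
#'   preserved.
#' @examples
#' race_table(data.frame(construct = "WT", dwell_s = 1.8, dwell_ci = 0.08,
#'                       run_length_um = 3.0, run_length_ci = 0.02))
#' @export
race_table <- function(rows, step_size = 8) {
  required <- c("construct", "dwell_s", "dwell_ci", "run_length_um",
                "run_length_ci")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    kr_stop(paste("missing columns:", paste(missing_cols, collapse = ", ")),
            "kinrace_validation_error")
  }
  out <- rows
  blank <- rep(NA_real_, nrow(rows))
  out$off_rate_s <- out$off_rate_ci <- out$steps <- out$steps_ci <-
    out$kon_th_s <- out$kon_th_ci <- blank
  out$error <- rep(NA_character_, nrow(rows))
  for (i in seq_len(nrow(rows))) {
    res <- tryCatch({
      dwell <- rate_estimate(rows$dwell_s[i], rows$dwell_ci[i], "second")
      rl <- rate_estimate(rows$run_length_um[i], rows$run_length_ci[i],
                          "micrometer")
      off <- off_rate_from_dwell(dwell)
      steps <- steps_from_run_length(rl, step_size)
      kon <- tethered_head_on_rate(off, steps)
      list(off = off, steps = steps, kon = kon)
    }, kinrace_error = function(e) e, error = function(e) e)
    if (inherits(res, "condition")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$off_rate_s[i] <- res$off$value
      out$off_rate_ci[i] <- res$off$ci95
      out$steps[i] <- res$steps$value
      out$steps_ci[i] <- res$steps$ci95
      out$kon_th_s[i] <- res$kon$value
      out$kon_th_ci[i] <- res$kon$ci95
    }
  }
  out
}

#' Render a race table at display precision
#'
#' Off-rates to 2 decimals, step counts and attachment rates to the nearest
#' integer, half rounded up; full precision is retained in the unrendered
#' table.
#'
#' @param tab output of [race_table()].
#' @return data frame of character columns `construct`, `dwell`, `off_rate`,
#'   `steps`, `kon_th` formatted as `value +/- ci`.
#' @export
format_race_table <- function(tab) {
  fmt <- function(v, ci, digits) {
    ifelse(is.na(v), "--",
           sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                   round_half_up(v, digits), round_half_up(ci, digits)))
  }
  data.frame(
    construct = tab$construct,
    dwell = fmt(tab$dwell_s, tab$dwell_ci, 1),
    off_rate = fmt(tab$off_rate_s, tab$off_rate_ci, 2),
    steps = fmt(tab$steps, tab$steps_ci, 0),
    kon_th = fmt(tab$kon_th_s, tab$kon_th_ci, 0),
    error = tab$error,
    stringsAsFactors = FALSE
  )
}
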