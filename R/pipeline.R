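#' @name pipeline
#' @title Orchestration: event tables, race reports, and the full workflow
#'
#' @description
#' I/O and composition over the other modules: validated CSV event tables,
#' the race-table report rendered at display precision, the per-buffer
#' charge/run-length regression, and the end-to-end
#' simulate -> censor -> fit -> race -> regress pipeline, deterministic for a
#' fixed seed, with a provenance block in every report.
NULL

#' Load and validate an event table CSV
#'
#' Required columns: `event_id`, `run_length_um`, `duration_s`; optional
#' `n_steps`, `velocity_um_s`, `dwell_s`, `censored`. Unit suffixes in the
#' column names are part of the contract (um, s).
#'
#' @param path CSV path.
#' @return validated data frame (possibly empty if only a header is present).
#' @export
load_event_table <- function(path) {
  if (!file.exists(path)) {
    kr_stop(sprintf("file not found: %s", path), "kinrace_validation_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("event_id", "run_length_um", "duration_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    kr_stop(paste("missing columns:", paste(missing_cols, collapse = ", ")),
            "kinrace_validation_error")
  }
  for (col in intersect(c("run_length_um", "duration_s", "dwell_s",
                          "velocity_um_s"), names(df))) {
    vals <- df[[col]]
    if (nrow(df) > 0 && !is.numeric(vals)) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals))))[1]
      kr_stop(sprintf("non-numeric value in column %s at row %d", col,
                      if (is.na(bad)) 1L else bad),
              "kinrace_validation_error")
    }
  }
  if (nrow(df) > 0) {
    bad <- which(df$duration_s <= 0)
    if (length(bad) > 0) {
      kr_stop(sprintf("nonpositive duration_s at row %d", bad[1]),
              "kinrace_validation_error")
    }
    bad <- which(df$run_length_um < 0)
    if (length(bad) > 0) {
      kr_stop(sprintf("negative run_length_um at row %d", bad[1]),
              "kinrace_validation_error")
    }
  }
  df
}

#' Race-table report section
#'
#' Runs [race_table()] on per-construct (dwell, run length) measurements and
#' renders the result at display precision (off-rates to 2 decimals, steps
#' and attachment rates to integers, half rounded up). Invalid rows are kept
#' and flagged.
#'
#' @param inputs data frame with columns `construct`, `dwell_s`, `dwell_ci`,
#'   `run_length_um`, `run_length_ci`.
#' @param step_size step size in nm (default 8).
#' @return list with `table` (full precision) and `rendered` (display
#'   strings).
#' @export
run_race_report <- function(inputs, step_size = 8) {
  tab <- race_table(inputs, step_size = step_size)
  list(table = tab, rendered = format_race_table(tab))
}

#' Charge vs run-length regression report
#'
#' For each buffer, joins ledger net charges to measured run lengths,
#' excludes non-processive constructs (`NA` run length, e.g. not detectable
#' in high ionic strength), and fits an unweighted OLS line of run length on
#' loop-12 net charge. Buffers with fewer than two usable points are skipped
#' with a notice.
#'
#' @param ledger data frame with `construct` and `net_charge` (see
#'   [kloop_ledger()]).
#' @param run_lengths data frame with columns `construct`, `buffer`,
#'   `run_length_um` (NA for non-processive), optional `run_length_ci`.
#' @param weighted if `TRUE` and `run_length_ci` is present, fit
#'   inverse-variance weighted instead of OLS.
#' @return list keyed by buffer: each entry has `fit` (a `linear_fit` or
#'   `NULL`), `points`, `excluded` (non-processive construct names), and
#'   `notice`.
#' @export
charge_runlength_report <- function(ledger, run_lengths, weighted = FALSE) {
  stopifnot(all(c("construct", "net_charge") %in% names(ledger)),
            all(c("construct", "buffer", "run_length_um") %in%
                  names(run_lengths)))
  out <- list()
  for (buf in unique(run_lengths$buffer)) {
    sub <- run_lengths[run_lengths$buffer == buf, ]
    sub <- merge(sub, ledger[, c("construct", "net_charge")],
                 by = "construct", sort = FALSE)
    excluded <- sub$construct[is.na(sub$run_length_um)]
    pts <- sub[!is.na(sub$run_length_um), ]
    if (nrow(pts) < 2) {
      out[[buf]] <- list(fit = NULL, points = pts, excluded = excluded,
                         notice = "fewer than 2 processive constructs; regression skipped")
      next
    }
    y_err <- if (weighted && "run_length_ci" %in% names(pts)) {
      pts$run_length_ci
    } else NULL
    fit <- fit_linear(pts$net_charge, pts$run_length_um, y_err = y_err)
    out[[buf]] <- list(fit = fit, points = pts, excluded = excluded,
                       notice = NA_character_)
  }
  out
}

#' Run the full simulate -> censor -> fit -> race -> regress pipeline
#'
#' Executes every enabled stage of a configuration and assembles a summary
#' report. The simulation stage draws processive runs from the kinetic race,
#' applies pixel censoring, fits the run-length distribution by truncated
#' maximum likelihood, and inverts the race to recover the tethered-head
#' attachment rate from the simulated off-rate and fitted run length; the
#' race stage reproduces a measurement-driven race table; the charge stage
#' regresses run length on loop-12 net charge. A stage failure is recorded
#' in the report without discarding earlier stages.
#'
#' @param config list with fields:
#'   * `seed`: integer, required when `simulation` is enabled;
#'   * `simulation`: list(`k_on_TH`, `k_detach`, `k_step`, `step_size` = 8,
#'     `n`) or `NULL` to disable;
#'   * `detection`: list passed to [detection_settings()] (optional);
#'   * `race_inputs`: data frame for [run_race_report()] or `NULL`;
#'   * `charge`: list(`ledger`, `run_lengths`) or `NULL`.
#' @param out_dir optional directory; when given, stage tables are written as
#'   CSV (full precision).
#' @return list of class `summary_report` with `provenance`, and per-stage
#'   entries `simulation`, `race`, `charge` (each `NULL` when disabled, or
#'   carrying `error` when failed).
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  if (!is.list(config)) {
    kr_stop("`config` must be a list", "kinrace_validation_error")
  }
  if (!is.null(config$simulation) && is.null(config$seed)) {
    kr_stop("a seed is required when the simulation stage is enabled",
            "kinrace_validation_error")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(
    provenance = list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("kinrace")),
      config_json = jsonlite::toJSON(
        config[setdiff(names(config), c("race_inputs", "charge"))],
        auto_unbox = TRUE, digits = NA)
    ),
    simulation = NULL, race = NULL, charge = NULL
  )
  run_stage <- function(expr) {
    tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
  }

  if (!is.null(config$simulation)) {
    report$simulation <- run_stage({
      sim <- config$simulation
      step_size <- if (is.null(sim$step_size)) 8 else sim$step_size
      rates <- cycle_rates(sim$k_on_TH, sim$k_detach, sim$k_step, step_size)
      det <- do.call(detection_settings,
                     if (is.null(config$detection)) list() else config$detection)
      runs <- simulate_processive_runs(rates, sim$n,
                                       seed = substream_seed(config$seed, "runs"))
      cens <- apply_detection_censoring(runs, det, axis = "distance")
      fit <- fit_exponential_truncated(cens$kept$run_length_um,
                                       cutoff = cens$cutoff)
      # invert the race: off-rate from the generating rates, steps from fit
      rl <- rate_estimate(fit$components$tau, fit$components$tau_ci95,
                          "micrometer")
      steps <- steps_from_run_length(rl, step_size)
      off <- rate_estimate(rates$k_detach, 0, "per_second")
      kon_hat <- tethered_head_on_rate(off, steps)
      if (!is.null(out_dir)) {
        utils::write.csv(runs, file.path(out_dir, "simulated_runs.csv"),
                         row.names = FALSE)
      }
      list(n_simulated = nrow(runs), n_removed = cens$n_removed,
           cutoff_um = cens$cutoff,
           fitted_run_length_um = fit$components$tau,
           fitted_run_length_ci = fit$components$tau_ci95,
           recovered_k_on_TH = kon_hat$value,
           recovered_k_on_TH_ci = kon_hat$ci95,
           true_k_on_TH = rates$k_on_TH, runs = cens$kept)
    })
  }

  if (!is.null(config$race_inputs)) {
    report$race <- run_stage({
      rep_ <- run_race_report(config$race_inputs)
      if (!is.null(out_dir)) {
        utils::write.csv(rep_$table, file.path(out_dir, "race_table.csv"),
                         row.names = FALSE)
      }
      rep_
    })
  }

  if (!is.null(config$charge)) {
    report$charge <- run_stage({
      reg <- charge_runlength_report(config$charge$ledger,
                                     config$charge$run_lengths)
      if (!is.null(out_dir)) {
        fits <- do.call(rbind, lapply(names(reg), function(buf) {
          f <- reg[[buf]]$fit
          if (is.null(f)) return(NULL)
          data.frame(buffer = buf, slope = f$slope,
                     slope_ci95 = f$slope_ci95, intercept = f$intercept,
                     intercept_ci95 = f$intercept_ci95, n = f$n)
        }))
        if (!is.null(fits)) {
          utils::write.csv(fits, file.path(out_dir, "charge_regression.csv"),
                           row.names = FALSE)
        }
      }
      reg
    })
  }

  structure(report, class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat("kinetic-race summary report (seed",
      if (is.null(x$provenance$seed)) "none" else x$provenance$seed,
      ", kinrace", x$provenance$package_version, ")\n")
  if (!is.null(x$simulation)) {
    s <- x$simulation
    if (!is.null(s$error)) {
      cat("  simulation: FAILED:", s$error, "\n")
    } else {
      cat(sprintf("  simulation: %d runs (%d censored), fitted RL %.3g um, recovered k_on_TH %.4g s^-1 (true %.4g)\n",
                  s$n_simulated, s$n_removed, s$fitted_run_length_um,
                  s$recovered_k_on_TH, s$true_k_on_TH))
    }
  }
  if (!is.null(x$race) && is.null(x$race$error)) {
    cat("  race table:\n")
    print(x$race$rendered, row.names = FALSE)
  }
  if (!is.null(x$charge) && is.null(x$charge$error)) {
    for (buf in names(x$charge)) {
      f <- x$charge[[buf]]$fit
      if (is.null(f)) {
        cat(sprintf("  charge regression [%s]: %s\n", buf,
                    x$charge[[buf]]$notice))
      } else {
        cat(sprintf("  charge regression [%s]: slope %.2f +/- %.2f um per unit charge\n",
                    buf, f$slope, f$slope_ci95))
      }
    }
  }
  invisible(x)
}
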