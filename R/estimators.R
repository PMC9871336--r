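#' @name estimators
#' @title Distribution and curve fitting for single-molecule kinetics
#'
#' @description
#' Fitting used throughout the analysis: left-truncated single- and
#' double-exponential maximum-likelihood fits to run-length and dwell-time
#' samples (the censored 1-CDF data of a kymograph analysis),
#' Michaelis-Menten and Langmuir saturation fits, (weighted) linear fits for
#' bimolecular on-rates and charge regressions, an automatic segmented
#' velocity estimator, and empirical survival curves. All estimators report
#' 95% confidence intervals.
NULL

#' Left-truncated exponential maximum-likelihood fit
#'
#' For an exponential distribution observed only above a detection cutoff,
#' the memoryless property makes the MLE of the time (or length) constant the
#' mean excess over the cutoff: `tau = mean(x - cutoff)` over `x >= cutoff`,
#' with 95% CI `1.96 * tau / sqrt(n_used)`. Samples below the cutoff are
#' excluded and counted.
#'
#' @param samples positive numeric values (run lengths in um or dwells in s).
#' @param cutoff left-truncation point in the same unit (default 0).
#' @param min_n minimum retained samples (default 5).
#' @return object of class `exponential_fit` with `components`
#'   (data frame: `weight`, `tau`, `tau_ci95`, `weight_ci95`), `n_used`,
#'   `n_input`, `cutoff`, `degenerate`, `converged`.
#' @examples
#' fit_exponential_truncated(c(2, 3, 4), cutoff = 1)  # tau = 2
#' @export
fit_exponential_truncated <- function(samples, cutoff = 0, min_n = 5) {
  if (length(samples) == 0 || any(!is.finite(samples)) || any(samples <= 0)) {
    kr_stop("samples must be positive and finite", "kinrace_domain_error")
  }
  if (cutoff < 0) kr_stop("`cutoff` must be >= 0", "kinrace_domain_error")
  kept <- samples[samples >= cutoff]
  if (length(kept) < min_n) {
    kr_stop(sprintf("only %d samples at or above the cutoff (need >= %d)",
                    length(kept), min_n), "kinrace_insufficient_data_error")
  }
  tau <- mean(kept - cutoff)
  ci <- 1.96 * tau / sqrt(length(kept))
  structure(list(
    components = data.frame(weight = 1, tau = tau, tau_ci95 = ci,
                            weight_ci95 = 0),
    n_used = length(kept), n_input = length(samples), cutoff = cutoff,
    degenerate = FALSE, converged = TRUE
  ), class = "exponential_fit")
}

# EM for a 2-component exponential mixture on nonnegative data
.em_two_exp <- function(y, w0, tau0, max_iter = 1000, tol = 1e-10) {
  w <- w0; tau <- tau0
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- cbind(w[1] / tau[1] * exp(-y / tau[1]),
                  w[2] / tau[2] * exp(-y / tau[2]))
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    r <- dens / rowsum_
    nj <- colSums(r)
    if (any(nj < 1e-8)) return(NULL)  # component starved
    w <- nj / length(y)
    tau <- colSums(r * y) / nj
    if (any(tau <= 0) || any(!is.finite(tau))) return(NULL)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) {
      return(list(w = w, tau = tau, loglik = ll, r = r, converged = TRUE))
    }
    ll_old <- ll
  }
  list(w = w, tau = tau, loglik = ll_old, r = r, converged = FALSE)
}

#' Left-truncated biexponential maximum-likelihood fit
#'
#' Fits a two-component exponential mixture to samples observed above a
#' detection cutoff. By memorylessness, shifting the retained samples by the
#' cutoff leaves a plain two-exponential mixture whose component weights are
#' reweighted by the truncation survival `exp(-cutoff/tau_j)`; the EM
#' estimates the shifted mixture, then the reported weights are corrected
#' back to the untruncated population. Components are ordered `tau1 < tau2`
#' and weights sum to 1. A fit with `tau1/tau2 > 0.9` is flagged
#' near-degenerate (the data do not support two timescales). Multi-start EM
#' from data quantiles makes the fit deterministic.
#'
#' @inheritParams fit_exponential_truncated
#' @param min_n minimum retained samples (default 50).
#' @param max_restarts maximum additional start points to try on
#'   non-convergence.
#' @return object of class `exponential_fit` with two component rows.
#' @export
fit_biexponential_truncated <- function(samples, cutoff = 0, min_n = 50,
                                        max_restarts = 8) {
  if (length(samples) == 0 || any(!is.finite(samples)) || any(samples <= 0)) {
    kr_stop("samples must be positive and finite", "kinrace_domain_error")
  }
  if (cutoff < 0) kr_stop("`cutoff` must be >= 0", "kinrace_domain_error")
  kept <- samples[samples >= cutoff]
  if (length(kept) < min_n) {
    kr_stop(sprintf("only %d samples at or above the cutoff (need >= %d)",
                    length(kept), min_n), "kinrace_insufficient_data_error")
  }
  y <- kept - cutoff
  y[y == 0] <- .Machine$double.eps  # exact-cutoff samples carry no excess
  q <- stats::quantile(y, c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  q <- pmax(q, mean(y) * 1e-3)
  starts <- list(c(q[2], q[6]), c(q[3], q[5]), c(q[1], q[4]),
                 c(mean(y) / 4, mean(y) * 2), c(mean(y) / 10, mean(y)),
                 c(q[4], q[6]), c(mean(y) / 2, mean(y) * 4),
                 c(q[1], q[6]), c(mean(y) / 20, mean(y) * 3))
  starts <- starts[seq_len(min(length(starts), 1 + max_restarts))]
  best <- NULL
  for (st in starts) {
    fit <- .em_two_exp(y, c(0.5, 0.5), sort(st))
    if (is.null(fit) || !fit$converged) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    kr_stop("biexponential EM failed to converge from all start points",
            "kinrace_convergence_error")
  }
  ord <- order(best$tau)
  tau <- best$tau[ord]
  w_trunc <- best$w[ord]
  nj <- colSums(best$r)[ord]
  # undo the truncation reweighting to report population weights
  w_pop <- w_trunc * exp(cutoff / tau)
  w_pop <- w_pop / sum(w_pop)
  tau_ci <- 1.96 * tau / sqrt(nj)
  w_ci <- 1.96 * sqrt(w_pop * (1 - w_pop) / length(y))
  # near-degenerate when the two timescales coincide, one component is
  # starved, or the mixture barely improves on a single exponential
  # (likelihood-ratio below the chi-square 95% point for 2 extra parameters)
  ll_single <- length(y) * (-log(mean(y)) - 1)
  degenerate <- (tau[1] / tau[2]) > 0.9 || any(w_trunc < 0.02) ||
    2 * (best$loglik - ll_single) < stats::qchisq(0.95, 2)
  structure(list(
    components = data.frame(weight = w_pop, tau = tau, tau_ci95 = tau_ci,
                            weight_ci95 = w_ci),
    n_used = length(kept), n_input = length(samples), cutoff = cutoff,
    degenerate = degenerate, converged = TRUE,
    loglik = best$loglik
  ), class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("truncated exponential fit (%d component%s), n = %d/%d, cutoff = %g\n",
              nrow(x$components), if (nrow(x$components) > 1) "s" else "",
              x$n_used, x$n_input, x$cutoff))
  print(x$components, row.names = FALSE)
  if (x$degenerate) cat("flag: near-degenerate (tau1/tau2 > 0.9)\n")
  invisible(x)
}

# shared machinery for 2-parameter saturation fits y = a*x/(b+x)
.fit_saturation <- function(x, y, a_name, b_name) {
  if (length(x) != length(y) || length(x) < 3) {
    kr_stop("need >= 3 (x, y) pairs", "kinrace_insufficient_data_error")
  }
  if (length(unique(x)) < 3) {
    kr_stop("need >= 3 distinct x values", "kinrace_design_error")
  }
  if (all(y == 0)) {
    out <- list(a = 0, b = NA_real_, a_ci95 = 0, b_ci95 = NA_real_,
                rss = 0, df = length(x) - 2, degenerate = TRUE)
    names(out)[1:4] <- c(a_name, b_name, paste0(a_name, "_ci95"),
                         paste0(b_name, "_ci95"))
    return(structure(out, class = "saturation_fit"))
  }
  a0 <- max(y) * 1.1
  half <- a0 / 2
  b0 <- x[which.min(abs(y - half))]
  if (b0 <= 0) b0 <- max(mean(x[x > 0]), 1e-6)
  df_ <- data.frame(x = x, y = y)
  fit <- minpack.lm::nlsLM(y ~ a * x / (b + x), data = df_,
                           start = list(a = a0, b = b0),
                           lower = c(0, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  rss <- sum(stats::resid(fit)^2)
  out <- list(unname(est["a"]), unname(est["b"]),
              unname(1.96 * se[1]), unname(1.96 * se[2]),
              rss = rss, df = length(x) - 2, degenerate = FALSE)
  names(out)[1:4] <- c(a_name, b_name, paste0(a_name, "_ci95"),
                       paste0(b_name, "_ci95"))
  structure(out, class = "saturation_fit")
}

#' Michaelis-Menten fit of observed rates vs substrate concentration
#'
#' Least-squares fit of `k_obs = k_max * x / (K_M + x)`, as used for
#' ATP-triggered half-site release curves; CIs are 1.96 times the asymptotic
#' standard errors from the fit covariance.
#'
#' @param x concentrations in uM (>= 3 distinct values).
#' @param y observed rates in s^-1.
#' @return object of class `saturation_fit` with `k_max`, `K_M`,
#'   `k_max_ci95`, `K_M_ci95`, `rss`, `df`, `degenerate` (TRUE when all
#'   responses are zero).
#' @export
fit_michaelis_menten <- function(x, y) {
  .fit_saturation(x, y, "k_max", "K_M")
}

#' Langmuir binding isotherm fit for pelleting assays
#'
#' Identical model to [fit_michaelis_menten()] with binding naming:
#' `fraction = V_max * [Mt] / (K_D + [Mt])`. Fractions above 1 are allowed
#' (normalization to an AMPPNP control is noisy).
#'
#' @param mt microtubule concentrations in uM (>= 3 distinct values).
#' @param fraction bound fractions.
#' @return object of class `saturation_fit` with `V_max`, `K_D` and CIs.
#' @export
fit_langmuir <- function(mt, fraction) {
  .fit_saturation(mt, fraction, "V_max", "K_D")
}

#' @export
print.saturation_fit <- function(x, ...) {
  nm <- names(x)[1:2]
  cat(sprintf("%s = %g +/- %g; %s = %g +/- %g (rss %.3g, df %d)%s\n",
              nm[1], x[[1]], x[[3]], nm[2], x[[2]], x[[4]], x$rss, x$df,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Linear fit with optional inverse-variance weighting
#'
#' Ordinary least squares, or weighted least squares with weights
#' `1 / y_err^2` when measurement errors are supplied; 95% CIs use the
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors; at least 2 distinct x values.
#' @param y_err optional positive per-point errors on `y`.
#' @return object of class `linear_fit` with `slope`, `intercept`,
#'   `slope_ci95`, `intercept_ci95`, `weighted`, `n`, `r_squared`.
#' @examples
#' fit_linear(c(4, 1, 0, -1), c(14.3, 6.7, 2.6, 1.2))  # slope ~2.7
#' @export
fit_linear <- function(x, y, y_err = NULL) {
  if (length(x) != length(y) || length(x) < 2) {
    kr_stop("need >= 2 (x, y) pairs", "kinrace_insufficient_data_error")
  }
  if (length(unique(x)) < 2) {
    kr_stop("all x values identical: slope is unidentifiable",
            "kinrace_design_error")
  }
  weighted <- !is.null(y_err)
  if (weighted) {
    if (length(y_err) != length(y) || any(y_err <= 0)) {
      kr_stop("`y_err` must be positive and match `y` in length",
              "kinrace_domain_error")
    }
    fit <- stats::lm(y ~ x, weights = 1 / y_err^2)
  } else {
    fit <- stats::lm(y ~ x)
  }
  # summary.lm warns on exact lines ("essentially perfect fit"); round-trip
  # tests feed exactly those
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  tcrit <- stats::qt(0.975, df = length(x) - 2)
  structure(list(
    slope = unname(co["x", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_ci95 = unname(tcrit * co["x", "Std. Error"]),
    intercept_ci95 = unname(tcrit * co["(Intercept)", "Std. Error"]),
    weighted = weighted, n = length(x),
    r_squared = sm$r.squared
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("slope = %g +/- %g, intercept = %g +/- %g (%s, n = %d, R2 = %.3f)\n",
              x$slope, x$slope_ci95, x$intercept, x$intercept_ci95,
              if (x$weighted) "weighted" else "OLS", x$n, x$r_squared))
  invisible(x)
}

#' Segmented velocity of a position trace
#'
#' Motors at low ionic strength pause frequently, so end-to-end velocity
#' underestimates the motile speed. This estimator splits a trace into
#' constant-velocity segments in two passes: (1) instantaneous speeds over a
#' 3-frame sliding window are classified as paused when below
#' `pause_speed_fraction` times the trace median speed; (2) contiguous motile
#' stretches are merged into segments (edges trimmed of sub-threshold
#' frames), and segments displacing less than
#' `min_segment_pixels * pixel_size_um` are dropped. Velocities are
#' per-segment displacement over duration.
#'
#' @param positions_um positions in um.
#' @param times_s times in s, non-decreasing, same length as `positions_um`.
#' @param min_segment_pixels minimum segment displacement in pixels.
#' @param pixel_size_um pixel size in um.
#' @param pause_speed_fraction pause threshold as a fraction of the trace
#'   median windowed speed (default 0.25).
#' @return list with `segments` (data frame: `start_s`, `end_s`,
#'   `displacement_um`, `velocity_um_s`), `mean_velocity`, `sem_velocity`,
#'   `end_to_end_velocity`.
#' @export
estimate_segmented_velocity <- function(positions_um, times_s,
                                        min_segment_pixels = 3,
                                        pixel_size_um = 0.0567,
                                        pause_speed_fraction = 0.25) {
  if (length(positions_um) != length(times_s) || length(times_s) < 2) {
    kr_stop("need >= 2 (position, time) points",
            "kinrace_insufficient_data_error")
  }
  if (any(diff(times_s) < 0)) {
    kr_stop("times must be non-decreasing", "kinrace_domain_error")
  }
  dt <- diff(times_s)
  dt[dt == 0] <- .Machine$double.eps
  v_raw <- diff(positions_um) / dt
  # 3-frame sliding window (running mean over up to 3 adjacent intervals)
  k <- length(v_raw)
  v_win <- vapply(seq_len(k), function(i) {
    idx <- max(1, i - 1):min(k, i + 1)
    mean(v_raw[idx])
  }, numeric(1))
  threshold <- pause_speed_fraction * stats::median(abs(v_win))
  motile <- abs(v_win) >= threshold
  runs <- rle(motile)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg_rows <- list()
  for (j in seq_along(runs$values)) {
    if (!runs$values[j]) next
    i0 <- starts[j]; i1 <- ends[j]
    # trim edges whose raw interval speed is itself sub-threshold
    while (i0 <= i1 && abs(v_raw[i0]) < threshold) i0 <- i0 + 1
    while (i1 >= i0 && abs(v_raw[i1]) < threshold) i1 <- i1 - 1
    if (i1 < i0) next
    disp <- positions_um[i1 + 1] - positions_um[i0]
    dur <- times_s[i1 + 1] - times_s[i0]
    if (abs(disp) < min_segment_pixels * pixel_size_um) next
    seg_rows[[length(seg_rows) + 1]] <-
      data.frame(start_s = times_s[i0], end_s = times_s[i1 + 1],
                 displacement_um = disp, velocity_um_s = disp / dur)
  }
  segments <- if (length(seg_rows) > 0) {
    do.call(rbind, seg_rows)
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0),
               displacement_um = numeric(0), velocity_um_s = numeric(0))
  }
  v <- segments$velocity_um_s
  list(
    segments = segments,
    mean_velocity = if (length(v) > 0) mean(v) else NA_real_,
    sem_velocity = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
    end_to_end_velocity =
      (positions_um[length(positions_um)] - positions_um[1]) /
      (times_s[length(times_s)] - times_s[1])
  )
}

#' Empirical survival (1-CDF) curve
#'
#' @param samples nonempty numeric vector.
#' @return data frame `value`, `survival` where `survival` is the fraction of
#'   samples at or above `value`; starts at 1 and ends at `1/n` (for distinct
#'   maxima).
#' @export
empirical_survival <- function(samples) {
  if (length(samples) == 0) {
    kr_stop("`samples` must be nonempty", "kinrace_insufficient_data_error")
  }
  v <- sort(unique(samples))
  data.frame(value = v,
             survival = vapply(v, function(z) mean(samples >= z), numeric(1)))
}
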