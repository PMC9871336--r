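#' @name synthetic_single_molecule
#' @title Seeded Monte-Carlo generator of single-molecule observables
#'
#' @description
#' Generates every data type the estimators consume: processive runs from the
#' per-cycle attachment/detachment race (geometric step counts, 8-nm steps,
#' exponential cycle times), single- and two-component exponential dwell
#' times, linear stopped-flow observed-rate curves, Michaelis-Menten
#' ATP-dependence curves, Langmuir pelleting curves, and the pixel/frame
#' detection-censoring operators that mimic what a kymograph analysis can
#' resolve. All generators are seeded and deterministic; with zero noise the
#' curve generators are exact closed-form evaluations.
NULL

#' Chemomechanical cycle rates for the run simulator
#'
#' @param k_on_TH tethered-head attachment rate, s^-1 (> 0).
#' @param k_detach detachment rate from the one-head-bound state, s^-1 (>= 0).
#' @param k_step overall stepping rate setting cycle durations, s^-1 (> 0);
#'   anchor: 1.7 um/s at 8 nm per step gives ~212 s^-1.
#' @param step_size step size in nm (default 8).
#' @return object of class `cycle_rates`.
#' @export
cycle_rates <- function(k_on_TH, k_detach, k_step, step_size = 8) {
  if (k_on_TH <= 0 || k_step <= 0 || k_detach < 0 || step_size <= 0) {
    kr_stop("require k_on_TH > 0, k_step > 0, k_detach >= 0, step_size > 0",
            "kinrace_domain_error")
  }
  structure(list(k_on_TH = k_on_TH, k_detach = k_detach, k_step = k_step,
                 step_size = step_size),
            class = "cycle_rates")
}

#' Simulate processive runs from the kinetic race
#'
#' Each cycle resolves to a forward step with probability
#' `k_on_TH / (k_on_TH + k_detach)` and to detachment otherwise, so the step
#' count per run is geometric with support starting at 0 (a motor may detach
#' before its first resolved step; such events fall below the pixel censor).
#' Run length is `n_steps * step_size`; duration is the sum of `n_steps + 1`
#' exponential cycle times at rate `k_step` (the final, detaching cycle also
#' takes time).
#'
#' @param rates a [cycle_rates()] object.
#' @param n number of runs (>= 0).
#' @param seed integer seed; identical `(rates, n, seed)` give identical
#'   tables.
#' @param max_steps guard on steps per run; required finite when
#'   `k_detach = 0`, otherwise `Inf`.
#' @return data frame with columns `event_id`, `n_steps`, `run_length_um`,
#'   `duration_s`, `velocity_um_s`, `censored` (all `FALSE`; set by
#'   [apply_detection_censoring()]).
#' @examples
#' runs <- simulate_processive_runs(cycle_rates(208, 0.56, 212), 100, seed = 1)
#' mean(runs$run_length_um)  # ~ (208/0.56) * 8 nm = 2.97 um
#' @export
simulate_processive_runs <- function(rates, n, seed = NULL, max_steps = Inf) {
  stopifnot(inherits(rates, "cycle_rates"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    kr_stop("`n` must be a nonnegative count", "kinrace_domain_error")
  }
  if (rates$k_detach == 0 && !is.finite(max_steps)) {
    kr_stop("k_detach = 0 needs a finite `max_steps` guard to terminate",
            "kinrace_nontermination_error")
  }
  n <- as.integer(n)
  empty <- data.frame(event_id = integer(0), n_steps = integer(0),
                      run_length_um = numeric(0), duration_s = numeric(0),
                      velocity_um_s = numeric(0), censored = logical(0))
  if (n == 0) return(empty)
  with_seed(seed, {
    p_detach <- detach_probability(rates$k_detach, rates$k_on_TH)
    n_steps <- if (p_detach == 0) rep(max_steps, n) else stats::rgeom(n, p_detach)
    n_steps <- pmin(n_steps, max_steps)
    duration <- stats::rgamma(n, shape = n_steps + 1, rate = rates$k_step)
    run_length <- n_steps * rates$step_size / 1000  # nm -> um
    data.frame(
      event_id = seq_len(n),
      n_steps = as.integer(n_steps),
      run_length_um = run_length,
      duration_s = duration,
      velocity_um_s = run_length / duration,
      censored = FALSE
    )
  })
}

#' Exponential dwell-time mixture specification
#'
#' @param weights probabilities summing to 1 (tolerance 1e-9).
#' @param taus time constants in seconds, all > 0; components are stored
#'   sorted by ascending tau.
#' @return object of class `dwell_mixture`.
#' @examples
#' dwell_mixture(c(0.4, 0.6), c(0.03, 0.3))  # fast/slow ADP dwell components
#' @export
dwell_mixture <- function(weights, taus) {
  if (length(weights) != length(taus) || length(taus) < 1) {
    kr_stop("`weights` and `taus` must be nonempty and of equal length",
            "kinrace_validation_error")
  }
  if (any(taus <= 0)) {
    kr_stop("all taus must be positive", "kinrace_validation_error")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    kr_stop("weights must be nonnegative and sum to 1 (tol 1e-9)",
            "kinrace_validation_error")
  }
  ord <- order(taus)
  structure(list(weights = weights[ord], taus = taus[ord]),
            class = "dwell_mixture")
}

#' Simulate dwell times from an exponential mixture
#'
#' @param mix a [dwell_mixture()].
#' @param n number of dwells (>= 0).
#' @param seed integer seed.
#' @return numeric vector of dwell times in seconds.
#' @export
simulate_dwell_times <- function(mix, n, seed = NULL) {
  stopifnot(inherits(mix, "dwell_mixture"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    kr_stop("`n` must be a nonnegative count", "kinrace_domain_error")
  }
  n <- as.integer(n)
  if (n == 0) return(numeric(0))
  with_seed(seed, {
    comp <- sample.int(length(mix$taus), n, replace = TRUE,
                       prob = mix$weights)
    stats::rexp(n, rate = 1 / mix$taus[comp])
  })
}

#' Detection settings for kymograph-style censoring
#'
#' Defaults mirror a TIRF analysis where traces shorter than 3 pixels along
#' the distance axis (ATP run lengths) or 3 frames along the time axis (ADP
#' dwells) cannot be scored: pixel size 0.0567 um makes the 3-pixel distance
#' cutoff 0.17 um, and the 10-fps frame interval makes the 3-frame time
#' cutoff 0.3 s. Presets for 50 fps (0.02 s) and 5 fps (0.2 s) acquisitions
#' are available via `frame_interval_s`.
#'
#' @param pixel_size_um pixel size in micrometers (> 0).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param min_pixels minimum trace extent in pixels (default 3).
#' @param min_frames minimum trace extent in frames (default 3).
#' @return object of class `detection_settings`.
#' @export
detection_settings <- function(pixel_size_um = 0.0567, frame_interval_s = 0.1,
                               min_pixels = 3L, min_frames = 3L) {
  vals <- c(pixel_size_um, frame_interval_s, min_pixels, min_frames)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    kr_stop("all detection settings must be positive",
            "kinrace_validation_error")
  }
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 min_pixels = as.integer(min_pixels),
                 min_frames = as.integer(min_frames)),
            class = "detection_settings")
}

#' Apply pixel/frame detection censoring
#'
#' Removes events the imaging analysis could not score: along the distance
#' axis, runs shorter than `min_pixels * pixel_size_um`; along the time axis,
#' durations (or plain dwell vectors) shorter than
#' `min_frames * frame_interval_s`. Kept events are unchanged and
#' `kept + removed = input`; the operation is idempotent.
#'
#' @param events event data frame from [simulate_processive_runs()], or a
#'   numeric vector of dwell times when `axis = "time"`.
#' @param settings a [detection_settings()].
#' @param axis `"distance"` or `"time"`.
#' @return list with `kept` (same type as `events`), `n_removed`, and the
#'   `cutoff` applied.
#' @export
apply_detection_censoring <- function(events, settings,
                                      axis = c("distance", "time")) {
  stopifnot(inherits(settings, "detection_settings"))
  if (!is.character(axis) || !all(axis %in% c("distance", "time"))) {
    kr_stop("`axis` must be \"distance\" or \"time\"", "kinrace_domain_error")
  }
  axis <- match.arg(axis)
  if (axis == "distance") {
    cutoff <- settings$min_pixels * settings$pixel_size_um
    if (is.data.frame(events)) {
      keep <- events$run_length_um >= cutoff
    } else {
      kr_stop("distance-axis censoring needs an event table",
              "kinrace_validation_error")
    }
  } else {
    cutoff <- settings$min_frames * settings$frame_interval_s
    if (is.data.frame(events)) {
      col <- if ("dwell_s" %in% names(events)) "dwell_s" else "duration_s"
      keep <- events[[col]] >= cutoff
    } else {
      keep <- events >= cutoff
    }
  }
  kept <- if (is.data.frame(events)) events[keep, , drop = FALSE] else events[keep]
  if (is.data.frame(kept)) rownames(kept) <- NULL
  list(kept = kept, n_removed = sum(!keep), cutoff = cutoff)
}

# shared constructor for paired concentration/response curves
.kinetics_curve <- function(x, y, x_name, y_name, truth) {
  structure(data.frame(x = x, y = y),
            x_name = x_name, y_name = y_name, truth = truth,
            class = c("kinetics_curve", "data.frame"))
}

#' Simulate stopped-flow observed rates vs microtubule concentration
#'
#' Models mant-ADP release rate-limited by microtubule binding:
#' `k_obs = k_on_Mt * [Mt] + k_basal`, plus additive Gaussian noise. With
#' `noise_sd = 0` the curve is exact.
#'
#' @param mt_concentrations_um microtubule concentrations in uM (>= 0).
#' @param k_on_Mt bimolecular on-rate, uM^-1 s^-1.
#' @param k_basal intercept rate, s^-1 (default 0).
#' @param noise_sd Gaussian noise SD on k_obs, s^-1 (>= 0).
#' @param seed integer seed.
#' @return a `kinetics_curve` data frame with columns `x` (uM) and `y` (s^-1).
#' @export
simulate_bimolecular_rates <- function(mt_concentrations_um, k_on_Mt,
                                       k_basal = 0, noise_sd = 0,
                                       seed = NULL) {
  if (any(mt_concentrations_um < 0)) {
    kr_stop("concentrations must be nonnegative", "kinrace_domain_error")
  }
  if (noise_sd < 0) kr_stop("`noise_sd` must be >= 0", "kinrace_domain_error")
  y <- k_on_Mt * mt_concentrations_um + k_basal
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  }
  .kinetics_curve(mt_concentrations_um, y, "mt_um", "k_obs_s",
                  list(k_on_Mt = k_on_Mt, k_basal = k_basal))
}

#' Simulate ATP-triggered half-site release rates
#'
#' `k_obs = k_max * [ATP] / (K_M + [ATP])` plus additive Gaussian noise; the
#' saturating rate is a proxy for tethered-head attachment.
#'
#' @param atp_concentrations_um ATP concentrations in uM (>= 0).
#' @param k_max saturating rate, s^-1 (> 0).
#' @param K_M Michaelis constant, uM (> 0).
#' @param noise_sd Gaussian noise SD, s^-1 (>= 0).
#' @param seed integer seed.
#' @return a `kinetics_curve` data frame (`x` in uM, `y` in s^-1).
#' @export
simulate_half_site_release <- function(atp_concentrations_um, k_max, K_M,
                                       noise_sd = 0, seed = NULL) {
  if (K_M <= 0 || k_max <= 0) {
    kr_stop("k_max and K_M must be positive", "kinrace_domain_error")
  }
  if (any(atp_concentrations_um < 0)) {
    kr_stop("concentrations must be nonnegative", "kinrace_domain_error")
  }
  if (noise_sd < 0) kr_stop("`noise_sd` must be >= 0", "kinrace_domain_error")
  y <- k_max * atp_concentrations_um / (K_M + atp_concentrations_um)
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  }
  .kinetics_curve(atp_concentrations_um, y, "atp_um", "k_obs_s",
                  list(k_max = k_max, K_M = K_M))
}

#' Simulate a microtubule pelleting (cosedimentation) binding curve
#'
#' Langmuir isotherm `fraction = V_max * [Mt] / (K_D + [Mt])` plus additive
#' Gaussian noise, clipped below at 0. Fractions are normalized to an
#' AMPPNP-bound control, so `V_max` may exceed 1 slightly.
#'
#' @param mt_concentrations_um microtubule concentrations in uM (>= 0).
#' @param K_D dissociation constant, uM (> 0).
#' @param V_max maximal bound fraction, in (0, 1.2].
#' @param noise_sd Gaussian noise SD on the fraction (>= 0).
#' @param seed integer seed.
#' @return a `kinetics_curve` data frame (`x` in uM, `y` a bound fraction).
#' @export
simulate_pelleting <- function(mt_concentrations_um, K_D, V_max,
                               noise_sd = 0, seed = NULL) {
  if (K_D <= 0) kr_stop("K_D must be positive", "kinrace_domain_error")
  if (V_max <= 0 || V_max > 1.2) {
    kr_stop("V_max must lie in (0, 1.2]", "kinrace_domain_error")
  }
  if (any(mt_concentrations_um < 0)) {
    kr_stop("concentrations must be nonnegative", "kinrace_domain_error")
  }
  if (noise_sd < 0) kr_stop("`noise_sd` must be >= 0", "kinrace_domain_error")
  y <- V_max * mt_concentrations_um / (K_D + mt_concentrations_um)
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
    y <- pmax(y, 0)
  }
  .kinetics_curve(mt_concentrations_um, y, "mt_um", "fraction_pellet",
                  list(K_D = K_D, V_max = V_max))
}
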