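# internal helpers shared across modules

# classed error so callers can condition on failure type
kr_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "kinrace_error", "error")))
}

#' Round half away from zero
#'
#' Rounds 0.5 up (62.5 -> 63) rather than to even as [round()] does; this is
#' the convention used when rendering summary tables, where step counts and
#' rate constants are displayed to fixed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state;
# seed = NULL leaves the global stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    kr_stop("`seed` must be a single integer or NULL", "kinrace_domain_error")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a reproducible per-stage substream seed from a root seed, keeping the
# result inside the 32-bit integer range
substream_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(runs = 101L, dwells = 211L, kobs = 307L, halfsite = 401L,
               pelleting = 503L)
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}
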