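test_that("truncated exponential MLE is the mean excess over the cutoff", {
  f <- fit_exponential_truncated(c(1, 2, 3), cutoff = 0, min_n = 3)
  expect_equal(f$components$tau, 2.0)
  expect_equal(f$components$tau_ci95, 1.96 * 2 / sqrt(3))
  g <- fit_exponential_truncated(c(2, 3, 4), cutoff = 1, min_n = 3)
  expect_equal(g$components$tau, 2.0)
  expect_error(fit_exponential_truncated(c(1, 2), cutoff = 0),
               class = "kinrace_insufficient_data_error")
  expect_error(fit_exponential_truncated(c(-1, 2, 3), min_n = 3),
               class = "kinrace_domain_error")
  # samples below the cutoff are excluded and counted
  h <- fit_exponential_truncated(c(0.1, 0.2, 2, 3, 4, 5, 6), cutoff = 1,
                                 min_n = 5)
  expect_equal(h$n_used, 5)
  expect_equal(h$n_input, 7)
})

test_that("truncated MLE is shift-equivariant", {
  set.seed(21)
  x <- rexp(500, 1 / 3)
  for (d in c(0.1, 1, 2.5)) {
    a <- fit_exponential_truncated(x, cutoff = 0.2)
    b <- fit_exponential_truncated(x + d, cutoff = 0.2 + d)
    expect_equal(a$components$tau, b$components$tau, tolerance = 1e-12)
    expect_equal(a$n_used, b$n_used)
  }
})

test_that("truncated MLE recovers the run-length constant from censored draws", {
  set.seed(77)
  x <- rexp(50000, 1 / 3.0)
  f <- fit_exponential_truncated(x, cutoff = 0.17)
  expect_lt(abs(f$components$tau - 3.0), 3 * 3.0 / sqrt(f$n_used))
})

test_that("fitted tau is within 10% of truth in >= 95% of noisy replicates", {
  ok <- vapply(1:200, function(i) {
    x <- with(list(), {set.seed(4000 + i); rexp(1000, 1 / 3.0)})
    f <- fit_exponential_truncated(x, cutoff = 0.17)
    abs(f$components$tau - 3.0) / 3.0 < 0.10
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("biexponential EM recovers two well-separated dwell components", {
  mix <- dwell_mixture(c(0.5, 0.5), c(0.03, 0.3))
  d <- simulate_dwell_times(mix, 5000, seed = 13)
  f <- fit_biexponential_truncated(d, cutoff = 0.02)
  expect_false(f$degenerate)
  expect_lt(abs(f$components$tau[1] - 0.03) / 0.03, 0.20)
  expect_lt(abs(f$components$tau[2] - 0.3) / 0.3, 0.20)
  expect_equal(sum(f$components$weight), 1, tolerance = 1e-12)
  expect_lt(f$components$tau[1], f$components$tau[2])
  # deterministic: same data, same answer
  f2 <- fit_biexponential_truncated(d, cutoff = 0.02)
  expect_equal(f$components, f2$components)
})

test_that("biexponential fit flags single-exponential data as degenerate", {
  d <- simulate_dwell_times(dwell_mixture(1, 1.8), 2000, seed = 14)
  f <- fit_biexponential_truncated(d, cutoff = 0)
  expect_true(f$degenerate)
  # and its collapsed answer matches the single-exponential MLE
  s <- fit_exponential_truncated(d, cutoff = 0)
  pooled <- sum(f$components$weight * f$components$tau)
  expect_equal(pooled, s$components$tau, tolerance = 0.05 * s$components$tau)
  expect_error(fit_biexponential_truncated(rexp(10, 1)),
               class = "kinrace_insufficient_data_error")
})

test_that("saturation fits recover noiseless parameters to 1e-6", {
  x <- c(10, 25, 50, 100, 200, 500, 1000, 2000)
  mm <- fit_michaelis_menten(x, 172 * x / (119 + x))
  expect_equal(mm$k_max, 172, tolerance = 1e-6)
  expect_equal(mm$K_M, 119, tolerance = 1e-6)

  mt <- c(0.25, 0.5, 1, 2, 4, 8, 16)
  lg <- fit_langmuir(mt, 0.97 * mt / (1.3 + mt))
  expect_equal(lg$V_max, 0.97, tolerance = 1e-6)
  expect_equal(lg$K_D, 1.3, tolerance = 1e-6)
  lg2 <- fit_langmuir(mt, 0.24 * mt / (5.1 + mt))
  expect_equal(lg2$V_max, 0.24, tolerance = 1e-6)
  expect_equal(lg2$K_D, 5.1, tolerance = 1e-6)
  # half-saturation identity
  expect_equal(0.97 * 1.3 / (1.3 + 1.3), 0.97 / 2)

  expect_error(fit_michaelis_menten(c(1, 1, 1), c(1, 2, 3)),
               class = "kinrace_design_error")
  z <- fit_michaelis_menten(x, rep(0, length(x)))
  expect_true(z$degenerate)
  expect_equal(z$k_max, 0)
})

test_that("linear fits match closed-form OLS and honour weights", {
  x <- seq(0.5, 5, by = 0.5)
  f <- fit_linear(x, 10.6 * x)
  expect_equal(f$slope, 10.6, tolerance = 1e-9)
  expect_equal(f$intercept, 0, tolerance = 1e-9)
  expect_false(f$weighted)

  g <- fit_linear(c(4, 1, 0, -1), c(14.3, 6.7, 2.6, 1.2))
  expect_equal(round_half_up(g$slope, 1), 2.7)
  expect_equal(g$slope, 37.9 / 14, tolerance = 1e-12)  # closed-form Sxy/Sxx

  h <- fit_linear(c(7, 4, 1), c(5.6, 3.0, 0.5))
  expect_equal(h$slope, 0.85, tolerance = 1e-12)

  w <- fit_linear(x, 10.6 * x, y_err = rep(0.5, length(x)))
  expect_true(w$weighted)
  expect_equal(w$slope, 10.6, tolerance = 1e-9)
  expect_error(fit_linear(c(2, 2), c(1, 3)), class = "kinrace_design_error")
})

test_that("segmented velocity separates pauses from motile stretches", {
  t <- seq(0, 3, by = 0.1)
  pos <- ifelse(t <= 1, 1.5 * t,
                ifelse(t <= 2, 1.5, 1.5 + 1.5 * (t - 2)))
  sv <- estimate_segmented_velocity(pos, t)
  expect_equal(nrow(sv$segments), 2)
  expect_equal(sv$mean_velocity, 1.5, tolerance = 0.05)
  expect_equal(sv$end_to_end_velocity, 1.0, tolerance = 1e-9)
  expect_gt(sv$mean_velocity, sv$end_to_end_velocity)

  # single linear trace: one segment at the true speed
  one <- estimate_segmented_velocity(1.5 * t, t)
  expect_equal(nrow(one$segments), 1)
  expect_equal(one$mean_velocity, 1.5, tolerance = 1e-9)

  # a sub-3-pixel segment is excluded from the mean
  t2 <- seq(0, 2, by = 0.1)
  pos2 <- ifelse(t2 <= 1, 2 * t2, 2)          # 2 um motile, then pause
  pos2[t2 > 1.9] <- 2 + (t2[t2 > 1.9] - 1.9)  # final 0.1 um blip < 0.17 um
  sv2 <- estimate_segmented_velocity(pos2, t2)
  expect_equal(nrow(sv2$segments), 1)
  expect_equal(sv2$segments$displacement_um[1], 2, tolerance = 0.05)
  expect_error(estimate_segmented_velocity(1, 1),
               class = "kinrace_insufficient_data_error")
})

test_that("empirical survival counts the fraction at or above each value", {
  s <- empirical_survival(c(1, 2, 3))
  expect_equal(s$survival, c(1, 2 / 3, 1 / 3))
  expect_equal(empirical_survival(rep(4, 5)),
               data.frame(value = 4, survival = 1))
  x <- rexp(50, 1)
  expect_equal(empirical_survival(x)$survival[1], 1)
  expect_error(empirical_survival(numeric(0)),
               class = "kinrace_insufficient_data_error")
})

test_that("truncated MLE and least-squares-on-survival agree on clean data", {
  set.seed(99)
  x <- rexp(20000, 1 / 2.5)
  mle <- fit_exponential_truncated(x, cutoff = 0.1)
  surv <- empirical_survival(x[x >= 0.1])
  ls <- fit_linear(surv$value - 0.1, log(surv$survival))
  expect_lt(abs(-1 / ls$slope - mle$components$tau), mle$components$tau_ci95 * 2)
})
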