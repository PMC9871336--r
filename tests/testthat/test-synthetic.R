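test_that("simulated runs are reproducible and obey the geometric race law", {
  rates <- wt_cycle_rates()
  a <- simulate_processive_runs(rates, 10000, seed = 5)
  b <- simulate_processive_runs(rates, 10000, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, simulate_processive_runs(rates, 10000, seed = 6)))

  # mean steps -> k_on_TH / k_detach within 3 SEM at n = 10,000
  mu <- rates$k_on_TH / rates$k_detach
  sem <- sqrt(mu * (mu + 1)) / sqrt(nrow(a))  # geometric variance ~ mu^2 + mu
  expect_lt(abs(mean(a$n_steps) - mu), 3 * sem)
  # run length/duration/velocity are consistent by construction
  expect_equal(a$run_length_um, a$n_steps * 8 / 1000)
  expect_equal(a$velocity_um_s, a$run_length_um / a$duration_s)
  expect_true(all(a$duration_s > 0))
})

test_that("run simulator edge cases behave", {
  expect_equal(nrow(simulate_processive_runs(wt_cycle_rates(), 0)), 0)
  expect_error(simulate_processive_runs(wt_cycle_rates(), -1),
               class = "kinrace_domain_error")
  # zero detachment needs a max-steps guard
  r0 <- cycle_rates(208, 0, 212)
  expect_error(simulate_processive_runs(r0, 10, seed = 1),
               class = "kinrace_nontermination_error")
  g <- simulate_processive_runs(r0, 10, seed = 1, max_steps = 50)
  expect_true(all(g$n_steps == 50))
  # overwhelming detachment: nearly all runs have 0-1 steps
  h <- simulate_processive_runs(cycle_rates(1, 1000, 212), 2000, seed = 2)
  expect_gt(mean(h$n_steps <= 1), 0.99)
})

test_that("dwell mixtures validate and sample with the right means", {
  expect_error(dwell_mixture(c(0.5, 0.4), c(0.1, 1)),
               class = "kinrace_validation_error")
  expect_error(dwell_mixture(c(0.5, 0.5), c(-0.1, 1)),
               class = "kinrace_validation_error")
  mix <- dwell_mixture(c(0.6, 0.4), c(0.3, 0.03))
  expect_equal(mix$taus, c(0.03, 0.3))      # sorted ascending
  expect_equal(mix$weights, c(0.4, 0.6))    # weights follow their taus

  single <- dwell_mixture(1, 1.8)
  d <- simulate_dwell_times(single, 20000, seed = 9)
  expect_lt(abs(mean(d) - 1.8), 3 * 1.8 / sqrt(20000))

  d2 <- simulate_dwell_times(mix, 50000, seed = 10)
  mean_true <- 0.4 * 0.03 + 0.6 * 0.3
  sd_true <- sqrt(0.4 * 2 * 0.03^2 + 0.6 * 2 * 0.3^2 - mean_true^2)
  expect_lt(abs(mean(d2) - mean_true), 3 * sd_true / sqrt(50000))
  expect_identical(d2, simulate_dwell_times(mix, 50000, seed = 10))
  expect_length(simulate_dwell_times(mix, 0), 0)
})

test_that("detection censoring removes sub-resolution events and conserves counts", {
  det <- detection_settings()  # 3 px * 0.0567 um = 0.17 um; 3 * 0.1 s = 0.3 s
  events <- data.frame(event_id = 1:4,
                       run_length_um = c(0.10, 0.1701, 2.5, 0.169),
                       duration_s = c(1, 2, 3, 4))
  res <- apply_detection_censoring(events, det, "distance")
  expect_equal(res$cutoff, 0.1701)
  expect_equal(res$kept$event_id, c(2L, 3L))
  expect_equal(nrow(res$kept) + res$n_removed, nrow(events))
  # idempotent
  again <- apply_detection_censoring(res$kept, det, "distance")
  expect_equal(again$n_removed, 0)
  expect_equal(again$kept, res$kept)

  dwells <- c(0.25, 0.35, 5)
  tres <- apply_detection_censoring(dwells, det, "time")
  expect_equal(tres$kept, c(0.35, 5))
  expect_equal(tres$n_removed, 1)

  empty <- apply_detection_censoring(numeric(0), det, "time")
  expect_length(empty$kept, 0)
  expect_equal(empty$n_removed, 0)
  expect_error(apply_detection_censoring(events, det, "space"),
               class = "kinrace_domain_error")
  expect_error(detection_settings(pixel_size_um = 0),
               class = "kinrace_validation_error")
})

test_that("noiseless curve generators are exact closed-form evaluations", {
  lin <- simulate_bimolecular_rates(c(1), 10.6)
  expect_equal(lin$y, 10.6, tolerance = 1e-12)
  expect_equal(simulate_bimolecular_rates(c(0), 5, k_basal = 2.5)$y, 2.5,
               tolerance = 1e-12)

  mm <- simulate_half_site_release(c(96), 154, 96)
  expect_equal(mm$y, 77, tolerance = 1e-12)
  expect_equal(simulate_half_site_release(c(2000), 154, 96)$y,
               154 * 2000 / 2096, tolerance = 1e-12)
  expect_lt(abs(simulate_half_site_release(c(1e7), 154, 96)$y - 154), 0.01)

  pel <- simulate_pelleting(c(0, 1.3), 1.3, 0.97)
  expect_equal(pel$y, c(0, 0.485), tolerance = 1e-12)
  expect_error(simulate_pelleting(c(1), 0, 0.9), class = "kinrace_domain_error")
  expect_error(simulate_pelleting(c(1), 1, 1.5), class = "kinrace_domain_error")
  expect_error(simulate_half_site_release(c(1), 154, -1),
               class = "kinrace_domain_error")
  expect_error(simulate_bimolecular_rates(c(-1), 10), class = "kinrace_domain_error")

  # noisy curves are seeded and clip pelleting fractions at zero
  n1 <- simulate_pelleting(rep(0, 50), 1, 0.5, noise_sd = 0.3, seed = 3)
  expect_true(all(n1$y >= 0))
  n2 <- simulate_bimolecular_rates(1:5, 10.6, noise_sd = 1, seed = 4)
  expect_identical(n2, simulate_bimolecular_rates(1:5, 10.6, noise_sd = 1, seed = 4))
})

test_that("simulator seeding does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_processive_runs(wt_cycle_rates(), 10, seed = 99))
  expect_equal(runif(1), before)
})
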