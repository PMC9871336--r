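test_that("detachment probability handles exact, approximate and edge cases", {
  expect_equal(detach_probability(1, 1), 0.5)
  expect_equal(detach_probability(0, 208), 0)
  expect_equal(detach_probability(0.56, 208), 0.56 / 208.56)
  expect_equal(detach_probability(0.56, 208, approximate = TRUE), 0.56 / 208)
  expect_error(detach_probability(0, 0), class = "kinrace_race_error")
  expect_error(detach_probability(-1, 208), class = "kinrace_domain_error")
})

test_that("run length in steps inverts the detachment probability", {
  expect_equal(run_length_in_steps_from_p(1), 1)
  expect_equal(run_length_in_steps_from_p(0.5), 2)
  expect_equal(run_length_in_steps_from_p(0.002692308), 1 / 0.002692308)
  expect_error(run_length_in_steps_from_p(0), class = "kinrace_domain_error")
  expect_error(run_length_in_steps_from_p(1.5), class = "kinrace_domain_error")
})

test_that("exact-mode race round trip is (kon + kd)/kd to machine precision", {
  set.seed(11)
  for (i in 1:50) {
    kd <- runif(1, 0.01, 50)
    kon <- runif(1, 0.01, 500)
    steps <- run_length_in_steps_from_p(detach_probability(kd, kon))
    expect_equal(steps, (kon + kd) / kd, tolerance = 1e-14)
    # approximate and exact forms agree to first order in p
    p <- detach_probability(kd, kon)
    if (p < 0.5) {
      pa <- detach_probability(kd, kon, approximate = TRUE)
      expect_lte(abs(p - pa) / pa, p + 1e-12)
    }
  }
})

test_that("step counts, off-rates and attachment rates follow the race algebra", {
  steps <- steps_from_run_length(rate_estimate(3.0, 0.02, "micrometer"))
  expect_equal(steps$value, 375)
  expect_equal(steps$ci95, 2.5)
  expect_equal(steps_from_run_length(rate_estimate(0.008, 0, "micrometer"))$value, 1)
  # non-default step size is honoured
  expect_equal(steps_from_run_length(rate_estimate(1.6, 0, "micrometer"),
                                     step_size = 16)$value, 100)

  off <- off_rate_from_dwell(rate_estimate(1.8, 0.08, "second"))
  expect_equal(round_half_up(off$value, 2), 0.56)
  expect_equal(round_half_up(off$ci95, 2), 0.02)
  expect_equal(off_rate_from_dwell(rate_estimate(1, 0, "second"))$value, 1)

  kon <- tethered_head_on_rate(off, steps)
  expect_equal(round_half_up(kon$value, 0), 208)
  expect_error(off_rate_from_dwell(rate_estimate(0, 0, "second")),
               class = "kinrace_domain_error")
})

test_that("affinity decomposition recovers the ADP detachment rate", {
  kd <- detach_rate_from_affinity(
    rate_estimate(1.7, 1.0, "micromolar"),
    rate_estimate(10.6, 0.5, "per_micromolar_per_second"))
  expect_equal(kd$unit, "per_second")
  expect_equal(round_half_up(kd$value, 0), 18)
  kd2 <- detach_rate_from_affinity(
    rate_estimate(7.2, 5.1, "micromolar"),
    rate_estimate(9.1, 2.5, "per_micromolar_per_second"))
  expect_equal(round_half_up(kd2$value, 0), 66)
  expect_error(detach_rate_from_affinity(
    rate_estimate(1.7, 0, "second"),
    rate_estimate(10.6, 0, "per_micromolar_per_second")),
    class = "kinrace_unit_error")
})

test_that("stepping rate and fold changes reproduce the headline arithmetic", {
  expect_equal(stepping_rate_from_velocity(1.7, 8), 212.5)
  expect_equal(stepping_rate_from_velocity(0, 8), 0)
  expect_equal(stepping_rate_from_velocity(0.8, 8), 100)
  expect_error(stepping_rate_from_velocity(1, 0), class = "kinrace_domain_error")

  fc <- fold_change(rate_estimate(3.0, 0.02, "micrometer"),
                    rate_estimate(0.5, 0.004, "micrometer"))
  expect_equal(fc$value, 6.0)
  expect_equal(fc$unit, "dimensionless")
  expect_equal(round_half_up(fold_change(
    rate_estimate(14.3, 0.4, "micrometer"),
    rate_estimate(3.0, 0.02, "micrometer"))$value, 2), 4.77)
  x <- rate_estimate(2, 0.2, "second")
  expect_equal(re_rel_ci(fold_change(x, x)), sqrt(2) * 0.1, tolerance = 1e-12)
  expect_error(fold_change(rate_estimate(1, 0, "second"),
                           rate_estimate(1, 0, "micrometer")),
               class = "kinrace_unit_error")
})

test_that("race_table reproduces the four-construct table at display precision", {
  tab <- race_table(table1_inputs())
  expect_true(all(is.na(tab$error)))
  expect_equal(round_half_up(tab$off_rate_s, 2), c(0.56, 3.33, 0.67, 0.71))
  expect_equal(round_half_up(tab$off_rate_s[2], 1), 3.3)
  expect_equal(round_half_up(tab$steps, 0), c(375, 63, 100, 113))
  expect_equal(round_half_up(tab$kon_th_s, 0), c(208, 208, 67, 80))
  # step-count CIs at displayed precision (2.5 -> 3 under half-up)
  expect_equal(round_half_up(tab$steps_ci, 0), c(3, 1, 3, 3))
  rendered <- format_race_table(tab)
  expect_equal(rendered$steps, c("375 ± 3", "63 ± 1", "100 ± 3", "113 ± 3"))
  expect_equal(rendered$kon_th[3], "67 ± 5")
})

test_that("race_table flags invalid rows and keeps processing", {
  rows <- table1_inputs()
  rows$dwell_s[2] <- 0
  tab <- race_table(rows)
  expect_false(is.na(tab$error[2]))
  expect_true(is.na(tab$kon_th_s[2]))
  expect_true(all(is.na(tab$error[-2])))
  expect_equal(round_half_up(tab$kon_th_s[1], 0), 208)
  expect_equal(nrow(race_table(table1_inputs()[0, ])), 0)
  expect_error(race_table(data.frame(construct = "x")),
               class = "kinrace_validation_error")
})
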