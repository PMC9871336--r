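#!/usr/bin/env Rscript
# Kinetic-race table: from measured ADP dwell times and ATP run lengths to
# tethered-head attachment rates for the four dimer constructs.
#
# Finding: the two KIF1A-based constructs share an attachment rate of
# ~208 s^-1 despite 6-fold different run lengths — the K-loop swap changes
# the detachment rate, not tethered-head attachment — while the kinesin-1
# backbones sit near 67-80 s^-1, three-fold slower.

library(kinrace)

dir.create("results", showWarnings = FALSE)

measurements <- data.frame(
  construct = c("1A_393", "1A-K1L12", "Kin1", "K1-1AL12"),
  dwell_s = c(1.8, 0.3, 1.5, 1.4),
  dwell_ci = c(0.08, 0.03, 0.1, 0.1),
  run_length_um = c(3.0, 0.5, 0.8, 0.9),
  run_length_ci = c(0.02, 0.004, 0.02, 0.02))

report <- run_race_report(measurements)
write.csv(report$table, "results/race_table.csv", row.names = FALSE)
write.table(report$rendered, "results/race_table_rendered.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Tethered-head attachment rates (off-rate x run length in 8-nm steps):\n")
print(report$rendered, row.names = FALSE)

# supporting arithmetic: the attachment rate race only matters because it is
# fast relative to the overall stepping rate
cat(sprintf("\nOverall stepping rate at 1.7 um/s: %.0f s^-1\n",
            floor(stepping_rate_from_velocity(1.7, 8))))
kdet <- detach_rate_from_affinity(
  rate_estimate(1.7, 1.0, "micromolar"),
  rate_estimate(10.6, 0.5, "per_micromolar_per_second"))
cat(sprintf("ADP-state detachment rate from K_D x k_on_Mt: %.0f +/- %.0f s^-1\n",
            round_half_up(kdet$value, 0), round_half_up(kdet$ci95, 0)))
fc <- fold_change(rate_estimate(3.0, 0.02, "micrometer"),
                  rate_estimate(0.5, 0.004, "micrometer"))
cat(sprintf("Run-length fold change on K-loop swap: %.1f-fold\n", fc$value))
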