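# shared fixtures: the four-construct race-table measurements and the
# per-buffer charge/run-length points used across tests

table1_inputs <- function() {
  data.frame(
    construct = c("1A_393", "1A-K1L12", "Kin1", "K1-1AL12"),
    dwell_s = c(1.8, 0.3, 1.5, 1.4),
    dwell_ci = c(0.08, 0.03, 0.1, 0.1),
    run_length_um = c(3.0, 0.5, 0.8, 0.9),
    run_length_ci = c(0.02, 0.004, 0.02, 0.02),
    stringsAsFactors = FALSE
  )
}

brb12_charge_points <- function() {
  data.frame(construct = c("WT", "K1L12", "4Q", "5Q"),
             buffer = "BRB12",
             net_charge = c(4, 1, 0, -1),
             run_length_um = c(14.3, 6.7, 2.6, 1.2))
}

brb80_charge_points <- function() {
  data.frame(construct = c("SuperK", "WT", "K1L12"),
             buffer = "BRB80",
             net_charge = c(7, 4, 1),
             run_length_um = c(5.6, 3.0, 0.5))
}

# cycle rates matching the WT construct: attachment 208 s^-1, detachment
# 0.56 s^-1, stepping 212 s^-1 (1.7 um/s over 8-nm steps)
wt_cycle_rates <- function() cycle_rates(208, 0.56, 212)
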