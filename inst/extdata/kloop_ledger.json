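{
  "description": "Loop-12 (K-loop) charge ledger for the KIF1A constructs: lysine count and integer net charge of the loop-12 domain at pH 6.9. k_substitutions_vs_wt gives the signed number of lysines added (+) or replaced by neutral residues (-) relative to WT for point-substitution mutants; the loop-swap construct K1L12 carries the kinesin-1 loop-12 sequence and is not a substitution series member.",
  "wt_construct": "WT",
  "entries": [
    {"construct": "WT",     "lysine_count": 6, "net_charge":  4, "k_substitutions_vs_wt": 0},
    {"construct": "SuperK", "lysine_count": 9, "net_charge":  7, "k_substitutions_vs_wt": 3},
    {"construct": "K1L12",  "lysine_count": 1, "net_charge":  1, "k_substitutions_vs_wt": null},
    {"construct": "4Q",     "lysine_count": 2, "net_charge":  0, "k_substitutions_vs_wt": -4},
    {"construct": "5Q",     "lysine_count": 1, "net_charge": -1, "k_substitutions_vs_wt": -5}
  ]
}
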