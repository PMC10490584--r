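{
  "beat": ["true_positive_pct", "false_positive_pct", "t_wave_pct",
           "precision_pct", "sensitivity_pct", "annotations_pct",
           "tp", "fp", "fn", "t_wave"],
  "breath": ["true_positive_pct", "false_positive_pct", "inaccurate_pct",
             "precision_pct", "sensitivity_pct", "annotations_pct",
             "phase_shift_s", "tp", "fp", "fn", "inaccurate"],
  "metrics": ["mae", "pe", "nrmse", "rho_p", "p_value", "rho_c", "n"]
}
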