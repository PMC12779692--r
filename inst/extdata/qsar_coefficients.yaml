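# Narcosis-type QSAR coefficients: log LC50 [mmol/L] = m * logKow + b.
# The values below are generic neutral-organic baseline-toxicity
# placeholders in the usual range for these endpoints; replace them with
# the calibrated coefficient set of the QSAR suite you are reproducing
# before interpreting absolute concentrations. kow_domain_max is the
# applicability-domain ceiling on logKow.
fish_96h_lc50:
  m: -0.85
  b: 1.70
  kow_domain_max: 5.0
daphnia_48h_lc50:
  m: -0.91
  b: 1.72
  kow_domain_max: 5.0
algae_96h_ec50:
  m: -0.90
  b: 1.80
  kow_domain_max: 6.4
fish_chv:
  m: -0.85
  b: 0.70
  kow_domain_max: 5.0
  chronic: true
daphnia_chv:
  m: -0.91
  b: 0.72
  kow_domain_max: 5.0
  chronic: true
algae_chv:
  m: -0.90
  b: 0.80
  kow_domain_max: 6.4
  chronic: true
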