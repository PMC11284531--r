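# SYNTHETIC calibration stand-in for a phenol O-H pKa linear free-energy
# model at the package's reference level of theory. The published study
# does not report its fit parameters or deprotonation free energies; the
# slope/intercept and per-compound dG values below were reverse-engineered
# so that pKa = slope * dG + intercept reproduces the reported pKa1 values
# (9.43 / 9.35 / 9.59). Do not reuse outside this regression context.
model:
  slope: 0.25           # 1/(kcal/mol)
  intercept: -60.0
  applicability_class: phenol O-H (synthetic calibration)
deprotonation_free_energy:   # kcal/mol, synthetic
  CMA: 277.72
  CMB: 277.40
  CMC: 278.36
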