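# Degrade-and-fire oscillator: mean peak height and period vs delay CV,
# with first-order and refined analytic predictions.
kind: oscillator_sweep
seed: 505
oscillator:
  lambda0: 40
  C0: 4
  hill: step
  delay: {family: gamma, mean: 2.0, cv: 0.2}
  beta_dil: 0.05
  gamma_enz: 4
  enz_cutoff: 2
cv_grid: [0.0, 0.2, 0.4, 0.6, 0.8]
n_osc: 200
out_dir: delayq-output/oscillator-sweep
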