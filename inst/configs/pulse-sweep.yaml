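# Incoherent feedforward loop: expected pulse duration vs delay sd.
kind: ffl_pulse
seed: 303
ffl:
  topology: incoherent
  K12: 8
  K13: 2
  K23: 5
  lambda1: 5
  lambda2: 5
  beta3: 5
  delay: {family: gamma, mean: 1.0, cv: 0.2}
sigma_grid: [0.0, 0.2, 0.4, 0.6, 0.8]
mode: both
n_rep: 800
out_dir: delayq-output/pulse-sweep
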