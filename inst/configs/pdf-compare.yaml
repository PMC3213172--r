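# Analytic signaling-time PDF vs Monte Carlo histogram (two-point delay:
# note the jump discontinuity inherited from the delay CDF).
kind: pdf_compare
seed: 202
delay: {family: two_point, mean: 1.0, sd: 0.5}
lambda: 1
K: 3
n_samples: 100000
n_bins: 200
out_dir: delayq-output/pdf-compare
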