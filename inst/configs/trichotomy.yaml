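# Conditional signaling time given exactly N initiations: increasing /
# flat / decreasing in delay sd as N crosses 2K - 1.
kind: trichotomy
seed: 404
delay: {family: two_point, mean: 1.0, sd: 0.0}
lambda: 1
K: 4
N_grid: [4, 5, 7, 9, 12]
sigma_grid: [0.2, 0.5, 0.8]
n_rep: 20000
out_dir: delayq-output/trichotomy
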