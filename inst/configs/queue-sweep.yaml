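# Mean signaling time vs delay variability, two-point delay.
kind: queue_sweep
seed: 101
delay: {family: two_point, mean: 1.0, sd: 0.0}
lambda: 10
K: [2, 5, 10]
sigma_grid: [0.0, 0.2, 0.4, 0.6, 0.8]
methods: [closed_form, quadrature, monte_carlo]
n_rep: 5000
out_dir: delayq-output/queue-sweep
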