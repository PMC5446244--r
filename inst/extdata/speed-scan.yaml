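# Tonic speed scan of the handcrafted 10-unit sequence network.
experiment: scan
seed: 1
network:
  n_units: 10
  eta: 0.1
  beta: 0.2
  tau_y: 20
  lam: 20
scan:
  x_hat_in: [0.4, 0.6, 0.8]
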