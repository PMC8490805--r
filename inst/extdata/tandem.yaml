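network: tandem.rules
seed: 1
rates:
  k0: 1.0
  k1: 0.2
  k2: 0.1
observation:
  nodes: [WAIT, TRANSIT]
  noise_sd: 0.1
filter:
  sigma0: 10
estimator:
  a: 0.1
  p0: 10000.0
  refresh: true
  burn_in_epochs: 60
  cadence: 30
synthetic:
  kind: sde
  q_process: 0.01
  duration_min: 480
  dt_min: 1
  u:
    u_arrivals: 2.0
  eta0: [5.0, 10.0]
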