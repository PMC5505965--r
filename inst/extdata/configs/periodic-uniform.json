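{
  "N": 1000,
  "memory_mode": "individual",
  "p": 0.9,
  "regime": "periodic",
  "period_n": 20,
  "initial_env": "random",
  "resident": {"mean": 0.6},
  "invader": {"kind": "uniform", "mean": 0.8, "sd": 0.057735026918962574},
  "m": 0.7,
  "max_generations": 10000,
  "n_replicates": 10000,
  "master_seed": 2017,
  "label": "periodic-uniform"
}
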