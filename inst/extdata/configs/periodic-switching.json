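{
  "N": 1000,
  "memory_mode": "switching",
  "q": 0.1,
  "regime": "periodic",
  "period_n": 10,
  "initial_env": "random",
  "resident": {"mean": 0.6},
  "invader": {"kind": "two_point", "mean": 0.8, "sd": 0.057735026918962574},
  "m": 0.7,
  "max_generations": 10000,
  "n_replicates": 10000,
  "master_seed": 2017,
  "label": "periodic-switching"
}
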