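{
  "N": 1000,
  "memory_mode": "individual",
  "p": 0.9,
  "regime": "constant",
  "resident": {"mean": 0.8},
  "invader": {"kind": "two_point", "mean": 0.8, "sd": 0.1},
  "max_generations": 10000,
  "n_replicates": 10000,
  "master_seed": 2017,
  "label": "constant-two-point"
}
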