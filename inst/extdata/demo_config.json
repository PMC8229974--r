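{
  "seed": 7,
  "amplicons": [
    {"name": "DR4_like", "n_cpg": 6,
     "profile": [0, 0, 0.3, 0.3, 0.9, 0.94]},
    {"name": "DR5_like", "n_cpg": 13,
     "profile": [0.02, 0.5, 0.9, 0.02, 0.5, 0.9, 0.02, 0.5, 0.9, 0.02, 0.5, 0.9, 0.02]}
  ],
  "read_sim": {"n_reads": 300},
  "caller": {"min_coverage": 50},
  "panel": {},
  "cohort": {"n_decoys": 10},
  "stages": {"simulate": true, "cohort": true}
}
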