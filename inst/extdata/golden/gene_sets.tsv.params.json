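{
  "RiboSET": {
    "top_n": 500,
    "post_filter_n": 4,
    "exclude_aug": true
  },
  "RiboSET_ext": {
    "top_n": 5000,
    "post_filter_n": 4,
    "exclude_aug": true
  },
  "PhyloSET": {
    "threshold": "total > 0",
    "scorer": "ng_llr_omega0.1"
  },
  "UntranslSET": {
    "min_ext_codons": 20,
    "max_ext_cov_frac": 0.0005,
    "min_cds_density": 1,
    "min_cds_cov_frac": 0.3,
    "n_input": 42,
    "n_selected": 28
  }
}
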