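{
  "smiles_max_len": 12,
  "protein_max_len": 16,
  "bpe_max_tokens": 8,
  "bpe_merges": 2,
  "embed_dim": 4,
  "drug_channels": [3, 4, 5],
  "drug_kernels": [2, 3, 3],
  "target_channels": [3, 4, 5],
  "target_kernels": [2, 3, 4],
  "d_model": 4,
  "n_heads": 2,
  "n_layers": 1,
  "ffn_dim": 6,
  "proj_channels": 4,
  "pool_bins": 3,
  "share_drug_branch_weights": false,
  "sfm_on_target_LG": false,
  "bfim_variant": "affine",
  "se_ratio": 4,
  "head_widths": [5, 4],
  "dropout": 0,
  "learning_rate": 0.001,
  "batch_size": 16,
  "epochs": 1,
  "folds": 2,
  "seed": 9,
  "architecture_variant": "mcf_dti",
  "decision_threshold": 0.5,
  "pooled_metrics": false,
  "early_stopping": false,
  "patience": 20,
  "pairs": "/tmp/Rtmpi7QeOO/fileb213342e7b5/nope.tsv",
  "ligands": null,
  "proteins": null,
  "affinity": null,
  "value_scale": "kd_nM",
  "checkpoint": null,
  "out_dir": ".",
  "n_pairs": 2000,
  "label_noise": 0,
  "small": false,
  "provenance": {
    "config_hash": "244874b3322272a266bf08b9cf81fd4f",
    "package_version": "0.1.0"
  }
}
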