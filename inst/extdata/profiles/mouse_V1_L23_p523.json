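{
  "species": "mouse",
  "region": "V1",
  "layer": "L23",
  "age_days": 523,
  "spine_rate": 1.8,
  "shaft_rate": 0.28,
  "filopodia_rate": 0.003,
  "soma_synapse_mean": 79.2,
  "axons_per_soma_mean": 39.3,
  "axon_synapse_rate": 0.86,
  "axon_branch_rate": 0.15,
  "bouton_volume_mean": 0.12,
  "vesicle_count_mean": 274,
  "mito_density_mean": 32000,
  "mito_synapse_corr": 0.5,
  "excitatory_shaft_fraction": 0.24,
  "mean_mito_size_um3": 0.068,
  "psd_logmean": 11.3329254649702,
  "psd_logsd": 0.6,
  "vesicle_cloud_logmean": 16.8260047738934,
  "vesicle_cloud_logsd": 0.5,
  "name": "mouse_V1_L23_p523"
}
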