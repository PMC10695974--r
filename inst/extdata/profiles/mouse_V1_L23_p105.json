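{
  "species": "mouse",
  "region": "V1",
  "layer": "L23",
  "age_days": 105,
  "spine_rate": 2.1,
  "shaft_rate": 0.25,
  "filopodia_rate": 0.005,
  "soma_synapse_mean": 72.2,
  "axons_per_soma_mean": 33,
  "axon_synapse_rate": 1.2,
  "axon_branch_rate": 0.22,
  "bouton_volume_mean": 0.12,
  "vesicle_count_mean": 274,
  "mito_density_mean": 32072.9,
  "mito_synapse_corr": 0.54,
  "excitatory_shaft_fraction": 0.24,
  "mean_mito_size_um3": 0.0687,
  "spine_offset_um": 1.081,
  "psd_logmean": 11.3319249646366,
  "psd_logsd": 0.6,
  "vesicle_cloud_logmean": 16.8242641294156,
  "vesicle_cloud_logsd": 0.5,
  "name": "mouse_V1_L23_p105"
}
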