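{
  "species": "mouse",
  "region": "V1",
  "layer": "L23",
  "age_days": 6,
  "spine_rate": 0.01,
  "shaft_rate": 0.064,
  "filopodia_rate": 0.7,
  "soma_synapse_mean": 1.2,
  "axons_per_soma_mean": 1.2,
  "axon_synapse_rate": 1.09,
  "axon_branch_rate": 0.09,
  "bouton_volume_mean": 0.04,
  "vesicle_count_mean": 27.4,
  "mito_density_mean": 12000,
  "mito_synapse_corr": 0.1,
  "excitatory_shaft_fraction": 0.24,
  "mean_mito_size_um3": 0.035,
  "psd_logmean": 10.6397782844103,
  "psd_logsd": 0.6,
  "vesicle_cloud_logmean": 16.4630992802041,
  "vesicle_cloud_logsd": 0.5,
  "name": "mouse_V1_L23_p6"
}
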