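{
  "species": "mouse",
  "region": "V1",
  "layer": "L23",
  "age_days": 36,
  "spine_rate": 1.63,
  "shaft_rate": 0.2,
  "filopodia_rate": 0.03,
  "soma_synapse_mean": 66,
  "axons_per_soma_mean": 25,
  "axon_synapse_rate": 0.9,
  "axon_branch_rate": 0.17,
  "bouton_volume_mean": 0.11,
  "vesicle_count_mean": 200,
  "mito_density_mean": 25000,
  "mito_synapse_corr": 0.35,
  "excitatory_shaft_fraction": 0.24,
  "mean_mito_size_um3": 0.055,
  "psd_logmean": 11.109781913656,
  "psd_logsd": 0.6,
  "vesicle_cloud_logmean": 16.7350329956877,
  "vesicle_cloud_logsd": 0.5,
  "name": "mouse_V1_L23_p36"
}
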