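{
  "species": "mouse",
  "region": "V1",
  "layer": "L23",
  "age_days": 14,
  "spine_rate": 0.87,
  "shaft_rate": 0.15,
  "filopodia_rate": 0.075,
  "soma_synapse_mean": 25.8,
  "axons_per_soma_mean": 17.25,
  "axon_synapse_rate": 0.71,
  "axon_branch_rate": 0.12,
  "bouton_volume_mean": 0.1,
  "vesicle_count_mean": 140,
  "mito_density_mean": 19236.2,
  "mito_synapse_corr": 0.2,
  "excitatory_shaft_fraction": 0.24,
  "mean_mito_size_um3": 0.04263,
  "spine_offset_um": 1.107,
  "psd_logmean": 10.8220998412042,
  "psd_logsd": 0.6,
  "vesicle_cloud_logmean": 16.6862428315183,
  "vesicle_cloud_logsd": 0.5,
  "name": "mouse_V1_L23_p14"
}
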