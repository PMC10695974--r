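{
  "species": "primate",
  "region": "V1",
  "layer": "L23",
  "age_days": 7,
  "spine_rate": 0.31,
  "shaft_rate": 0.1,
  "filopodia_rate": 0.9,
  "soma_synapse_mean": 15.8,
  "axons_per_soma_mean": 13.3,
  "axon_synapse_rate": 0.93,
  "axon_branch_rate": 0.16,
  "bouton_volume_mean": 0.08,
  "vesicle_count_mean": 180,
  "mito_density_mean": 15000,
  "mito_synapse_corr": 0.2,
  "excitatory_shaft_fraction": 0.24,
  "mean_mito_size_um3": 0.05,
  "soma_radius_um": 8,
  "psd_logmean": 10.9762505210315,
  "psd_logsd": 0.6,
  "vesicle_cloud_logmean": 16.5808823158604,
  "vesicle_cloud_logsd": 0.5,
  "name": "primate_V1_L23_p7"
}
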