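{
  "species": "primate",
  "region": "V1",
  "layer": "L23",
  "age_days": 3000,
  "spine_rate": 0.86,
  "shaft_rate": 0.25,
  "filopodia_rate": 0.002,
  "soma_synapse_mean": 16.1,
  "axons_per_soma_mean": 12.5,
  "axon_synapse_rate": 0.46,
  "axon_branch_rate": 0.22,
  "bouton_volume_mean": 0.27,
  "vesicle_count_mean": 250,
  "mito_density_mean": 30000,
  "mito_synapse_corr": 0.4,
  "excitatory_shaft_fraction": 0.24,
  "mean_mito_size_um3": 0.065,
  "soma_radius_um": 8,
  "psd_logmean": 11.4282356447746,
  "psd_logsd": 0.6,
  "vesicle_cloud_logmean": 16.7815530113226,
  "vesicle_cloud_logsd": 0.5,
  "name": "primate_V1_L23_p3000"
}
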