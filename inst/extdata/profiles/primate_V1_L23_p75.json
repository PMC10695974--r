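{
  "species": "primate",
  "region": "V1",
  "layer": "L23",
  "age_days": 75,
  "spine_rate": 2.44,
  "shaft_rate": 0.2,
  "filopodia_rate": 0.02,
  "soma_synapse_mean": 50.3,
  "axons_per_soma_mean": 22.4,
  "axon_synapse_rate": 1,
  "axon_branch_rate": 0.38,
  "bouton_volume_mean": 0.16,
  "vesicle_count_mean": 250,
  "mito_density_mean": 28000,
  "mito_synapse_corr": 0.4,
  "excitatory_shaft_fraction": 0.24,
  "mean_mito_size_um3": 0.06,
  "soma_radius_um": 8,
  "psd_logmean": 11.2275649493124,
  "psd_logsd": 0.6,
  "vesicle_cloud_logmean": 16.7815530113226,
  "vesicle_cloud_logsd": 0.5,
  "name": "primate_V1_L23_p75"
}
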