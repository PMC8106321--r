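# Example pipeline configuration.  Keys under `synthetic:` override
# synthetic_config() defaults; keys under `pipeline:` override
# pipeline_config() defaults (mcmc: takes mcmc_settings() arguments).
synthetic:
  n_states: 4
  districts_per_state: 3
  villages_per_district: 60
  cluster_fraction: 0.25
  seed: 1
pipeline:
  radius_km: 5
  iterations: 5
  k: 10
  mcmc:
    burn_in: 500
    n_iter: 5000
    seed: 1
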