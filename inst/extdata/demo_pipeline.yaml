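# Demo pipeline configuration: small synthetic run exercising every stage.
seed: 1
plate:
  simulate: true
  n_samples: 2
  n_days: 60
  step_h: 24
  ref_time: auto
community:
  simulate: true
  n_samples: 16
  n_asvs: 40
  n_guilds: 4
  within_guild_rho: 0.95
  group: layer
  n_perm: 199
network:
  stratum: layer
  top: 40
  r_threshold: 0.6
  alpha: 0.05
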