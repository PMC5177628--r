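# Study conditions and verification threshold for the parameter-recovery
# simulation (dominant-compartment identification). The threshold is a
# property of the estimator verified under these conditions, not a claim
# about external data.
recovery_config <- list(
  n_metabolites = 200L,
  n_replicates = 3L,
  f = 6L,
  noise_cv = 0.05,
  dominant_weight_min = 0.6,
  min_recovery_rate = 0.80,
  seed = 20260920L
)
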