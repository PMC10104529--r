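# Synthetic species thermal-trait prior config (cool-water archetype).
# These are illustrative package defaults patterned on laboratory tolerance
# values typical of cool-water inland-lake fishes, not literature estimates.
species: cool-water archetype (synthetic)
t_opt_mean: 24.0
t_opt_sd: 1.5
ct_max_mean: 31.0
ct_max_sd: 1.5
ct_min_mean: 4.0
# Optional hook: a truncated-normal prior on the Gaussian-limb scale sigma.
# sigma is fixed at (t_opt_mean - ct_min_mean)/4 when sigma_sd is 0.
sigma_sd: 0.0
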