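# exoload demo configuration: one `stage.key: value` per line.
# Unlisted keys keep their defaults; unknown keys are rejected.
global.seed: 7
global.out_dir: exoload_demo
simulate.n_samples: 44
simulate.n_variants: 300
simulate.n_host_pairs: 30
simulate.n_sites_per_context: 200
simulate.h2: 0.4
simulate.ambiguous_fraction: 0.1
dmr.n_extreme: 10
enrich.n_perm: 200
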