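# Example simulation config for the gsbench CLI: a reduced population that
# runs in seconds. Any sim_config() field may appear here; omitted fields
# keep their defaults (the full benchmark design).
n_sires: 2
n_dams: 4
n_offspring: 10
n_phenotyped_families: 4
markers_per_chromosome: [40, 40]
pool_haplotypes: 60
burnin_generations: 40
h2: 0.5
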