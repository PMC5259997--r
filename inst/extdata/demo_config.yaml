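# Demo pipeline configuration: a 12x12-block synthetic city with 200
# participants in 20 recruitment clusters, all three buffer methods at the
# 25 m trim, pooled analysis.
synth:
  n_participants: 200
  n_clusters: 20
  city:
    grid_blocks: [12, 12]
    block_size: 100
    edge_prune_prob: 0.1
    limited_access_fraction: 0.03
seed: 7
trims: 25
methods: [sausage, detailed_trimmed, detailed]
snapped: true
resolution: 3
strata: pooled
alpha: 0.05
cutoff: 1000
out_dir: bufcomp_demo_out
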