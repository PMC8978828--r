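Synthetic demonstration fixture (no real sequencing data).

demo_counts.tsv : 24 samples x 15 taxa count table drawn from the package's
  sparse-count simulator (scenario syn2, d = 15, 12/12 design, seed 42); the
  first taxon carries a planted relative-abundance shift between classes.
demo_meta.tsv   : matching metadata with sample_id, label (c1/c2) and a
  synthetic host column (two samples per host, hosts nested in class) for
  exercising block-restricted permutations.
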