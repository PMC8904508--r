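# Demo run: simulate a small three-population cohort with an outgroup,
# call pseudo-haploid genotypes from the pileup, screen relatedness and
# compute an outgroup-f3. All randomness derives from `seed`.
seed: 7
out: demo-out
stages: [simulate, call, relate, fstat]
simulate:
  n_snps: 4000
  n_chrom: 2
  chrom_length_mb: 50
  graph:
    edges:
      - root O 0.0
      - root X 0.02
      - X A 0.01
      - X B 0.01
  groups: {O: 2, A: 3, B: 3}
  mean_depth: 2
call:
  mode: double_strand
relate:
  min_overlap: 1000
fstat:
  statistic: f3
  pops:
    - [O, A, B]
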