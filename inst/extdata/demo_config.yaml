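# Demonstration pipeline configuration: a 5 vs 5 extreme-phenotype
# simulated cohort with a dominantly carried causal cis-haplotype
# (penetrance 0.9), followed by diversity scoring, the three-stage
# co-segregation filter cascade, association statistics and the
# expression-enrichment test.
seed: 42
simulate:
  n_affected: 5
  n_unaffected: 5
  penetrance: 0.9
  phenocopy: 0.0
  carrier_freq: 0.41
  background_variants: 150
  expression:
    upshift: 2
    n_background_genes: 500
    noise_sd: 0.5
diversity:
  k: 3
  groups: [affected, unaffected]
filter:
  stages: [[5, 0], [4, 1], [4, 0]]
  missing_policy: as_noncarrier
assoc:
  prevalence: 0.5
enrich:
  expression_floor: 7
  p_threshold: 0.05
  fc_threshold: 1.25
  expected_mode: rounded_counts
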