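# Association-only configuration on published herd carrier counts:
# herd 1: 15/20 affected and 4/21 unaffected animals carried the
# variant pair; herd 2 (replication): 11/15 affected, 4/16 unaffected.
seed: 1
assoc:
  prevalence: 0.5
  tables:
    herd1: [15, 5, 4, 17]
    herd2: [11, 4, 4, 12]
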