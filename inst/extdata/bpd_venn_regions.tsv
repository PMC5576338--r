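region	n
genotype_only	61
oxygen_only	4074
interaction_only	673
genotype_oxygen	99
genotype_interaction	26
oxygen_interaction	868
genotype_oxygen_interaction	164
none	0
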