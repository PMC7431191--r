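# colDL1.3/Df embryo segment phenotypes (n = 190 segments): 85.2% DA3>DA2
# transformed is the published figure; the split of the remaining 14.8%
# across the other categories is a package choice.
type: phenotype
genotype: colDL1.3
group_n: 190
normal: 0.02
branched: 0.06
transformed: 0.852
absent: 0.068
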