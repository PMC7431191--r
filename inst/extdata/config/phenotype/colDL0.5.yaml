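# colDL0.5/Df embryo segment phenotypes (n = 103 segments): 29% branched is
# the published figure; the remaining split is a package choice.
type: phenotype
genotype: colDL0.5
group_n: 103
normal: 0.55
branched: 0.29
transformed: 0.13
absent: 0.03
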