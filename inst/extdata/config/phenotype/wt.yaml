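# control (+/Df) embryo segment phenotypes (n = 127 segments): essentially
# all normal DA3; exact split is a package choice.
type: phenotype
genotype: wt
group_n: 127
normal: 0.98
branched: 0.02
transformed: 0
absent: 0
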