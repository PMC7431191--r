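# colDL1.3/Df larval crawling parameters (n = 112). The published report
# gives no numbers for this genotype beyond "intermediate"; means are the
# midpoints of the two published genotypes, sds comparable.
type: kinematics
genotype: colDL1.3
group_n: 112
walking_rate_mean: 1.10
stride_length_mean: 1.125
stride_length_sd: 0.26
stride_duration_mean: 1.12
stride_duration_sd: 0.16
heading_sd: 0.15
fps: 5
duration: 20
pause_prob: 0
pause_duration: 0.5
spine_length_rest: 4
contraction_amplitude: 0.15
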