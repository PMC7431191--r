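# control (+/Df) larval crawling parameters; group values from the published
# cohort (n = 118): walking rate 1.15 +/- 0.031 mm/s, stride length
# 1.17 +/- 0.024 mm, stride duration 1.09 +/- 0.014 s. Per-cycle sds are the
# between-larva SD, i.e. SEM * sqrt(n).
type: kinematics
genotype: control
group_n: 118
walking_rate_mean: 1.15
stride_length_mean: 1.17
stride_length_sd: 0.26071
stride_duration_mean: 1.09
stride_duration_sd: 0.15208
heading_sd: 0.15
fps: 5
duration: 20
pause_prob: 0
pause_duration: 0.5
spine_length_rest: 4
contraction_amplitude: 0.15
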