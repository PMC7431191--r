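# colDL0.5/Df larval crawling parameters (n = 108): walking rate
# 1.05 +/- 0.034 mm/s, stride length 1.08 +/- 0.025 mm, stride duration
# 1.15 +/- 0.017 s. sds = SEM * sqrt(n).
type: kinematics
genotype: colDL0.5
group_n: 108
walking_rate_mean: 1.05
stride_length_mean: 1.08
stride_length_sd: 0.25981
stride_duration_mean: 1.15
stride_duration_sd: 0.17667
heading_sd: 0.15
fps: 5
duration: 20
pause_prob: 0
pause_duration: 0.5
spine_length_rest: 4
contraction_amplitude: 0.15
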