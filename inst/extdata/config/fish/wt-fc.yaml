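# wild-type founder-cell stage col/nau ratio: 2.20 +/- 0.05 SEM, n = 28.
# ratio_sd = SEM * sqrt(n).
type: fish
genotype: wt-fc
group_n: 28
n_nuclei: 28
ratio_mean: 2.20
ratio_sd: 0.26458
nau_amplitude_mean: 50000
background_level: 50
psf_sigma: 1.5
noise_model: poisson
gaussian_sd: 10
stack_shape: [12, 256, 256]
nucleus_radii: [3, 6, 6]
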