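# colDL0.5 founder-cell stage col/nau ratio: 1.41 +/- 0.04 SEM, n = 25.
type: fish
genotype: colDL0.5-fc
group_n: 25
n_nuclei: 25
ratio_mean: 1.41
ratio_sd: 0.2
nau_amplitude_mean: 50000
background_level: 50
psf_sigma: 1.5
noise_model: poisson
gaussian_sd: 10
stack_shape: [12, 256, 256]
nucleus_radii: [3, 6, 6]
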