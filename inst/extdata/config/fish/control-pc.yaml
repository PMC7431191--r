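# control progenitor-cell stage col/nau ratio: 1.22 +/- 0.06 SEM, n = 18.
type: fish
genotype: control-pc
group_n: 18
n_nuclei: 18
ratio_mean: 1.22
ratio_sd: 0.25456
nau_amplitude_mean: 50000
background_level: 50
psf_sigma: 1.5
noise_model: poisson
gaussian_sd: 10
stack_shape: [12, 256, 256]
nucleus_radii: [3, 6, 6]
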