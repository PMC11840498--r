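# Example synthetic-cohort scenario: the drifting-editing regime with a
# reduced grid for quick runs.
preset: drift
seed: 1
n_periods: 9
patients_per_period: 10
grid_shape: [32, 32, 32]
spacing_mm: [1.0, 1.0, 2.5]
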