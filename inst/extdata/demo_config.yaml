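# Demo analysis: 5 short sequential-protocol trials at reduced resolution.
# Runs the full simulate -> segment -> estimate -> transition -> report
# pipeline in well under a minute on one CPU.
seed: 42
n_trials: 5
trial_length: 45.0
first_onset: 6.0
cycle_noise_sd: 0.01
spans: [3, 4]
n_groups: 5
n_resample: 100
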