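# Demo configuration: a small four-physician, two-arm cohort with a
# 2000-cycle simulated historical reference.
seed: 42
n_per_arm_per_physician: 20
n_physicians: 4
treatment_effect: 0.5
n_reference: 2000
agree_rate_dose: 0.63
agree_rate_trigger: 0.78
unavailable_rate: 0.045
k: 100
k_impute: 10
degree: 2
bootstrap_reps: 200
dose_step: 37.5
n_dose_curves: 3
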