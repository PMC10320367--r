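# Example configuration for a small synthetic validation study.
# Any study_config() argument may appear here; `seed` is mandatory.
n_patients: 40
prop_pediatric: 0.33
treatment_effect: 0.8
p_exact: 0.8
reread_fraction: 0.15
adjudication_threshold: 5
seed: 20260923
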