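# Synthetic example feature-domain hierarchy (reduced scale): seven broad
# level-1 domains over 24 synthetic feature names, with nested level-2
# sub-domains. Pair with a dataset whose columns carry these names, e.g.
#   simulate_features(n, p = 24, seed, feature_names = <these names>)
levels:
  level1:
    demographics: [age, sex, education]
    measured_risk: [bmi, height, systolic_bp, diastolic_bp, fev, fvc]
    polysomnography: [ahi, min_sao2, sleep_efficiency, waso, pct_rem]
    health_behaviors: [smoking_packyears, alcohol_use]
    selfreport_sleep: [snoring, sleepiness, insomnia]
    selfreport_medical: [hypertension_dx, diabetes_dx, sf36_physical]
    medications: [bp_medication, statin_use]
  level2:
    anthropometry: [bmi, height]
    blood_pressure: [systolic_bp, diastolic_bp]
    lung_function: [fev, fvc]
    sleep_disordered_breathing: [ahi, min_sao2]
    sleep_continuity: [sleep_efficiency, waso]
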