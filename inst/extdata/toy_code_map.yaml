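# Toy diagnosis-code map for tests and examples. The real study's 27-variable
# ICD-10 groupings live in a non-public supplement; supply your own map for
# production use (code -> indicator variable name).
I10: dx_hypertension
I11: dx_hypertension
E11: dx_diabetes
E10: dx_diabetes
C50: dx_cancer
C61: dx_cancer
F32: dx_mood_disorders
F31: dx_mood_disorders
F41: dx_anxiety
A51: dx_syphilis
A52: dx_syphilis
A54: dx_gonorrhea
A56: dx_chlamydia
B18: dx_hepatitis_b
B182: dx_hepatitis_c
F10: dx_sud_alcohol
F11: dx_sud_opioid
F12: dx_sud_cannabis
F17: dx_sud_tobacco
J44: dx_pulmonary
J45: dx_pulmonary
N18: dx_kidney_disease
K70: dx_liver_disease
O09: dx_pregnancy
E66: dx_obesity
F20: dx_psychosis
F60: dx_personality_disorders
I25: dx_cardiovascular
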