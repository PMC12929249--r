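{"visit_id":"N1","text":"Patient reports depression and is pregnant."}
{"visit_id":"N2","text":"No depression noted today."}
{"visit_id":"N3","text":"No history of chronic severe depression."}
{"visit_id":"N4","text":"Screening today. Patient denies any cocaine exposure currently, also no heroin."}
{"visit_id":"N5","text":"Syphilis neg today. Repeat testing found gonorrhea positive."}
{"visit_id":"N6","text":"Neg for chlamydia."}
{"visit_id":"N7","text":"Routine follow up visit."}
{"visit_id":"N8","text":"Patient is adherent, hypertension well controlled."}
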