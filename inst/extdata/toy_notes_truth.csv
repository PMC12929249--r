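visit_id,opportunistic_infection,comorbidities,poor_adherence,good_adherence,sexual_gender_minorities,heterosexual,life_stressors,mental_illness,pregnancy,preventive_health,sti,substance_use_disorder
N1,0,0,0,0,0,0,0,1,1,0,0,0
N2,0,0,0,0,0,0,0,0,0,0,0,0
N3,0,0,0,0,0,0,0,1,0,0,0,0
N4,0,0,0,0,0,0,0,0,0,1,0,1
N5,0,0,0,0,0,0,0,0,0,0,1,0
N6,0,0,0,0,0,0,0,0,0,0,0,0
N7,0,0,0,0,0,0,0,0,0,0,0,0
N8,0,1,0,1,0,0,0,0,0,0,0,0
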