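{
  "opportunistic_infection": {
    "include": ["pneumocystis", "toxoplasmosis", "cryptococcal meningitis", "opportunistic infection"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "comorbidities": {
    "include": ["hypertension", "diabetes", "asthma", "copd"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "poor_adherence": {
    "include": ["missed doses", "poor adherence", "nonadherent"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "good_adherence": {
    "include": ["good adherence", "takes medications daily", "adherent"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "sexual_gender_minorities": {
    "include": ["msm", "transgender", "bisexual"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "heterosexual": {
    "include": ["heterosexual"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "life_stressors": {
    "include": ["homeless", "unemployed", "food insecurity", "incarcerated"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "mental_illness": {
    "include": ["depression", "schizophrenia", "bipolar"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "pregnancy": {
    "include": ["pregnant", "pregnancy", "prenatal"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "preventive_health": {
    "include": ["vaccination", "screening", "prophylaxis"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "sti": {
    "include": ["gonorrhea", "chlamydia", "syphilis", "trichomoniasis"],
    "exclude": ["no", "neg"],
    "window": 3
  },
  "substance_use_disorder": {
    "include": ["cocaine", "heroin", "substance use", "methamphetamine"],
    "exclude": ["no", "neg"],
    "window": 3
  }
}
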