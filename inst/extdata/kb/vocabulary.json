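{"tags":[{"tag_id":"opioid_physical_dependence","label":"Known or suspected opioid physical dependence"},{"tag_id":"tdm","label":"Therapeutic drug monitoring performed"},{"tag_id":"skin_test","label":"Skin test performed"},{"tag_id":"cyp2d6_test","label":"CYP2D6 gene polymorphism testing performed"},{"tag_id":"pharmacogenetic_test","label":"Pharmacogenetic testing performed"},{"tag_id":"repeat_dose_scheduled","label":"Repeat dose scheduled"},{"tag_id":"drug_resistant_tb","label":"Drug-resistant tuberculosis"},{"tag_id":"tuberculosis","label":"Tuberculosis"},{"tag_id":"cystic_fibrosis","label":"Cystic fibrosis"},{"tag_id":"congenital_toxoplasmosis","label":"Congenital toxoplasmosis"},{"tag_id":"pertussis","label":"Bordetella pertussis infection"},{"tag_id":"chlamydia_trachomatis_pneumonia","label":"Chlamydia trachomatis pneumonia"},{"tag_id":"iv_bolus","label":"Administered as an intravenous bolus"},{"tag_id":"skin_test_waived_by_insert","label":"Package insert waives the skin test"},{"tag_id":"metabolic_disease","label":"Metabolic disease"},{"tag_id":"mitochondrial_disease","label":"Mitochondrial disease"},{"tag_id":"organ_transplantation","label":"Organ transplantation recipient"},{"tag_id":"nephrotic_syndrome","label":"Nephrotic syndrome"},{"tag_id":"acute_uri","label":"Acute upper respiratory tract infection"},{"tag_id":"symptoms_lt_4_days","label":"Symptoms present for fewer than 4 days"},{"tag_id":"bilateral_acute_otitis_media","label":"Bilateral acute otitis media"},{"tag_id":"acute_otitis_media","label":"Acute otitis media"},{"tag_id":"otorrhoea","label":"Otorrhoea"},{"tag_id":"acute_pharyngitis","label":"Acute pharyngitis"},{"tag_id":"acute_tonsillitis","label":"Acute tonsillitis"},{"tag_id":"acute_sore_throat","label":"Acute sore throat"},{"tag_id":"streptococcal_pharyngitis","label":"Streptococcal pharyngitis"},{"tag_id":"sinusitis","label":"Sinusitis"},{"tag_id":"centor_ge_3","label":"Three or more CENTOR criteria present"},{"tag_id":"crp_or_neutrophils_elevated","label":"Significantly increased CRP or neutrophil proportion"},{"tag_id":"bacterial_infection_confirmed","label":"Examinations suggest bacterial infection"},{"tag_id":"influenza","label":"Influenza"},{"tag_id":"chickenpox","label":"Chickenpox (varicella)"},{"tag_id":"acute_suppurative_otitis_media","label":"Acute suppurative otitis media"},{"tag_id":"nasopharyngitis","label":"Nasopharyngitis"},{"tag_id":"respiratory_infection","label":"Respiratory infection"},{"tag_id":"chronic_respiratory_disease","label":"Chronic respiratory disease"},{"tag_id":"anaphylaxis","label":"Anaphylaxis"},{"tag_id":"amox_penv_allergy","label":"Allergy to amoxicillin and penicillin V"},{"tag_id":"penicillin_allergy","label":"Penicillin allergy"},{"tag_id":"asthma","label":"Asthma"},{"tag_id":"bronchiolitis","label":"Bronchiolitis"},{"tag_id":"acute_cough","label":"Acute cough"},{"tag_id":"acute_bronchitis","label":"Acute bronchitis"},{"tag_id":"general_discomfort","label":"General discomfort"},{"tag_id":"severe_comorbidity","label":"Severe comorbidity"},{"tag_id":"immunocompromised","label":"Immunocompromised"},{"tag_id":"tonsillectomy_adenoidectomy","label":"After tonsillectomy and adenoidectomy"},{"tag_id":"asymptomatic_bacteriuria","label":"Asymptomatic bacterial urinary tract infection"},{"tag_id":"uti_initial_uncomplicated","label":"Initial urinary tract infection without complications"},{"tag_id":"antibiotic_prophylaxis","label":"Antibiotic prophylaxis intent"},{"tag_id":"uropathy","label":"Uropathy"},{"tag_id":"atopic_eczema","label":"Atopic eczema"},{"tag_id":"application_site_face_axilla_groin","label":"Applied to face, axilla, groin or back"},{"tag_id":"severe_lichenification","label":"Severe lichenification"},{"tag_id":"acne","label":"Acne vulgaris"},{"tag_id":"fusidic_acid_allergy","label":"Fusidic acid allergy"},{"tag_id":"impetigo","label":"Impetigo"},{"tag_id":"scabies","label":"Scabies"},{"tag_id":"herpes_simplex","label":"Herpes simplex"},{"tag_id":"ringworm","label":"Ringworm (tinea)"},{"tag_id":"gastroesophageal_reflux","label":"Gastroesophageal reflux"},{"tag_id":"indigestion","label":"Indigestion"},{"tag_id":"unexplained_crying","label":"Crying without any other signs or symptoms"},{"tag_id":"syncope","label":"Syncope"},{"tag_id":"feeding_difficulties","label":"Feeding difficulties"},{"tag_id":"pain","label":"Pain"},{"tag_id":"growth_retardation","label":"Growth retardation"},{"tag_id":"nausea","label":"Nausea"},{"tag_id":"vomiting","label":"Vomiting"},{"tag_id":"dehydration","label":"Dehydration"},{"tag_id":"shock","label":"Shock"},{"tag_id":"red_flag_symptoms","label":"Red flag symptoms despite ORS"},{"tag_id":"persistent_vomiting_ors","label":"Persistent vomiting of ORS"},{"tag_id":"diarrhea","label":"Diarrhea"},{"tag_id":"acute_infectious_diarrhea","label":"Acute infectious diarrhea"},{"tag_id":"antibiotic_associated_diarrhea","label":"Antibiotic-associated diarrhea"},{"tag_id":"septicemia_suspected","label":"Suspected or confirmed septicemia"},{"tag_id":"extraintestinal_bacterial_spread","label":"Extra-intestinal spread of bacterial infection"},{"tag_id":"salmonella_gastroenteritis","label":"Salmonella gastroenteritis"},{"tag_id":"malnourished","label":"Malnourished"},{"tag_id":"c_difficile_colitis","label":"Clostridium difficile-related pseudomembranous enterocolitis"},{"tag_id":"giardiasis","label":"Giardiasis"},{"tag_id":"shigella_dysentery","label":"Shigella dysentery"},{"tag_id":"amoebic_dysentery","label":"Amoebic dysentery"},{"tag_id":"cholera","label":"Cholera"},{"tag_id":"nocturnal_enuresis","label":"Enuresis (nocturnal)"},{"tag_id":"enuresis_daytime_only","label":"Enuresis with only daytime symptoms"},{"tag_id":"daytime_symptoms","label":"Daytime urinary symptoms"},{"tag_id":"adhd","label":"Attention deficit disorder with or without hyperactivity"},{"tag_id":"severe_condition","label":"Severe condition"},{"tag_id":"psychosis","label":"Psychosis or schizophrenia"},{"tag_id":"initial_treatment","label":"Initial treatment episode"},{"tag_id":"absence_seizures","label":"Epileptic absence seizures"},{"tag_id":"myoclonic_epilepsy","label":"Myoclonic epilepsy"},{"tag_id":"uncontrolled_seizures","label":"Uncontrolled seizures"},{"tag_id":"adverse_reaction_suspected","label":"Obvious suspected adverse reaction"},{"tag_id":"unidentified_self_medication","label":"Self-administered unidentified medicines"},{"tag_id":"depression","label":"Depression"},{"tag_id":"anorexia_nervosa","label":"Anorexia nervosa"},{"tag_id":"medication_primary_treatment","label":"Medication as sole or primary treatment"},{"tag_id":"destructive_aggressive_behavior","label":"Destructive or aggressive behaviors"},{"tag_id":"autism","label":"Autism"},{"tag_id":"emotional_problems","label":"Emotional problems"},{"tag_id":"bipolar_disorder","label":"Bipolar disorder"},{"tag_id":"fever","label":"Fever"},{"tag_id":"temp_below_38_2","label":"Axillary temperature below 38.2 C"},{"tag_id":"no_obvious_discomfort","label":"No obvious discomfort"},{"tag_id":"migraine","label":"Migraine"}]}
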