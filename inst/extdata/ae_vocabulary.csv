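"preferred_term","ae_group"
"ABASIA","ABASIA"
"ACCIDENT","ACCIDENT"
"ACUTE KIDNEY INJURY","ACUTE KIDNEY INJURY"
"AGGRESSION","AGGRESSION"
"AGRANULOCYTOSIS","AGRANULOCYTOSIS"
"AMNESIA","AMNESIA"
"ANAEMIA","ANAEMIA"
"ANAPHYLACTIC REACTION","ANAPHYLACTIC REACTION"
"ANAPHYLACTIC SHOCK","ANAPHYLACTIC REACTION"
"ANAPHYLACTOID REACTION","ANAPHYLACTOID REACTION"
"ANGINA PECTORIS","ANGINA PECTORIS"
"ANGIOEDEMA","ANGIOEDEMA"
"APLASTIC ANAEMIA","APLASTIC ANAEMIA"
"APNOEA","APNOEA"
"ARRHYTHMIA","ARRHYTHMIA"
"ATRIOVENTRICULAR BLOCK","ATRIOVENTRICULAR BLOCK"
"AZOTAEMIA","AZOTAEMIA"
"BACTERIAL INFECTION","BACTERIAL INFECTION"
"BLINDNESS","BLINDNESS"
"BONE MARROW FAILURE","BONE MARROW FAILURE"
"BRADYCARDIA","BRADYCARDIA"
"BRONCHITIS","BRONCHITIS"
"CANDIDA INFECTION","CANDIDA INFECTION"
"CARDIAC ARREST","CARDIAC ARREST"
"CARDIAC FAILURE","CARDIAC FAILURE"
"CARDIAC FAILURE CONGESTIVE","CARDIAC FAILURE"
"CARDIOMYOPATHY","CARDIOMYOPATHY"
"CATARACT","CATARACT"
"CELLULITIS","CELLULITIS"
"CEREBELLAR HAEMORRHAGE","CEREBRAL HAEMORRHAGE"
"CEREBRAL HAEMORRHAGE","CEREBRAL HAEMORRHAGE"
"HAEMORRHAGE INTRACRANIAL","CEREBRAL HAEMORRHAGE"
"CEREBRAL INFARCTION","CEREBRAL INFARCTION"
"CEREBROVASCULAR ACCIDENT","CEREBROVASCULAR ACCIDENT"
"TRANSIENT ISCHAEMIC ATTACK","CEREBROVASCULAR ACCIDENT"
"CHOLESTASIS","CHOLESTASIS"
"COAGULOPATHY","COAGULOPATHY"
"COLITIS","COLITIS"
"COLITIS ULCERATIVE","COLITIS ULCERATIVE"
"CONFUSIONAL STATE","CONFUSIONAL STATE"
"CONJUNCTIVITIS","CONJUNCTIVITIS"
"CROHN'S DISEASE","CROHN'S DISEASE"
"DEAFNESS","DEAFNESS"
"DEEP VEIN THROMBOSIS","DEEP VEIN THROMBOSIS"
"DELIRIUM","DELIRIUM"
"DELUSION","DELUSION"
"DERMATITIS BULLOUS","DERMATITIS BULLOUS"
"DERMATITIS EXFOLIATIVE","DERMATITIS EXFOLIATIVE"
"DIABETES MELLITUS","DIABETES MELLITUS"
"DIPLOPIA","DIPLOPIA"
"DISORIENTATION","DISORIENTATION"
"DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS","DRUG REACTION WITH EOSINOPHILIA AND SYSTEMIC SYMPTOMS"
"DYSGEUSIA","DYSGEUSIA"
"ELECTROCARDIOGRAM QT PROLONGED","ELECTROCARDIOGRAM QT PROLONGED"
"TORSADE DE POINTES","ELECTROCARDIOGRAM QT PROLONGED"
"EMBOLISM","EMBOLISM"
"EOSINOPHILIA","EOSINOPHILIA"
"ERYTHEMA MULTIFORME","ERYTHEMA MULTIFORME"
"EXTRAPYRAMIDAL DISORDER","EXTRAPYRAMIDAL DISORDER"
"FALL","FALL"
"FEBRILE NEUTROPENIA","FEBRILE NEUTROPENIA"
"FRACTURE","FRACTURE"
"FUNGAL INFECTION","FUNGAL INFECTION"
"GASTRIC ULCER","GASTRIC ULCER"
"PEPTIC ULCER","GASTRIC ULCER"
"GASTROINTESTINAL HAEMORRHAGE","GASTROINTESTINAL HAEMORRHAGE"
"GLAUCOMA","GLAUCOMA"
"GRANULOCYTOPENIA","GRANULOCYTOPENIA"
"HAEMATOMA","HAEMATOMA"
"HAEMOLYTIC ANAEMIA","HAEMOLYTIC ANAEMIA"
"HAEMORRHAGE","HAEMORRHAGE"
"HALLUCINATION","HALLUCINATION"
"HEPATIC FAILURE","HEPATIC FAILURE"
"HEPATIC NECROSIS","HEPATIC NECROSIS"
"HEPATITIS","HEPATITIS"
"HEPATOTOXICITY","HEPATOTOXICITY"
"LIVER INJURY","HEPATOTOXICITY"
"HOSTILITY","HOSTILITY"
"HYPERCHOLESTEROLAEMIA","HYPERCHOLESTEROLAEMIA"
"HYPERLIPIDAEMIA","HYPERCHOLESTEROLAEMIA"
"BLOOD GLUCOSE INCREASED","HYPERGLYCAEMIA"
"HYPERGLYCAEMIA","HYPERGLYCAEMIA"
"AKATHISIA","HYPERKINESIA"
"DYSKINESIA","HYPERKINESIA"
"DYSTONIA","HYPERKINESIA"
"HYPERKINESIA","HYPERKINESIA"
"HYPERTONIA","HYPERKINESIA"
"TARDIVE DYSKINESIA","HYPERKINESIA"
"HYPERSENSITIVITY","HYPERSENSITIVITY"
"HYPERTENSION","HYPERTENSION"
"HYPOGLYCAEMIA","HYPOGLYCAEMIA"
"IMPAIRED HEALING","IMPAIRED HEALING"
"INFECTION","INFECTION"
"INJURY","INJURY"
"INSOMNIA","INSOMNIA"
"INTERSTITIAL LUNG DISEASE","INTERSTITIAL LUNG DISEASE"
"JAUNDICE","JAUNDICE"
"JAUNDICE CHOLESTATIC","JAUNDICE"
"LARYNGEAL OEDEMA","LARYNGEAL OEDEMA"
"LEUKOPENIA","LEUKOPENIA"
"MEMORY IMPAIRMENT","MEMORY IMPAIRMENT"
"ACUTE MYOCARDIAL INFARCTION","MYOCARDIAL INFARCTION"
"MYOCARDIAL INFARCTION","MYOCARDIAL INFARCTION"
"MYOPATHY","MYOPATHY"
"MYOSITIS","MYOSITIS"
"NEUROLEPTIC MALIGNANT SYNDROME","NEUROLEPTIC MALIGNANT SYNDROME"
"NEUROPATHY PERIPHERAL","NEUROPATHY PERIPHERAL"
"PARAESTHESIA","NEUROPATHY PERIPHERAL"
"NEUTROPENIA","NEUTROPENIA"
"OEDEMA","OEDEMA"
"OEDEMA PERIPHERAL","OEDEMA"
"OLIGURIA","OLIGURIA"
"PANCREATITIS","PANCREATITIS"
"PANCREATITIS ACUTE","PANCREATITIS"
"PANCYTOPENIA","PANCYTOPENIA"
"PARALYSIS","PARALYSIS"
"PARANOIA","PARANOIA"
"PHOTOSENSITIVITY REACTION","PHOTOSENSITIVITY REACTION"
"PNEUMONIA","PNEUMONIA"
"PROTEINURIA","PROTEINURIA"
"PULMONARY EMBOLISM","PULMONARY EMBOLISM"
"PULMONARY OEDEMA","PULMONARY OEDEMA"
"RECTAL HAEMORRHAGE","RECTAL HAEMORRHAGE"
"RENAL FAILURE","RENAL FAILURE"
"RENAL IMPAIRMENT","RENAL IMPAIRMENT"
"RESPIRATORY DEPRESSION","RESPIRATORY DEPRESSION"
"RESPIRATORY ARREST","RESPIRATORY FAILURE"
"RESPIRATORY FAILURE","RESPIRATORY FAILURE"
"RHABDOMYOLYSIS","RHABDOMYOLYSIS"
"ROAD TRAFFIC ACCIDENT","ROAD TRAFFIC ACCIDENT"
"EPILEPSY","SEIZURE"
"SEIZURE","SEIZURE"
"SEPSIS","SEPSIS"
"SEPTIC SHOCK","SEPSIS"
"SEROTONIN SYNDROME","SEROTONIN SYNDROME"
"SKIN ULCER","SKIN ULCER"
"SLEEP DISORDER","SLEEP DISORDER"
"STEVENS-JOHNSON SYNDROME","STEVENS-JOHNSON SYNDROME"
"STOMATITIS","STOMATITIS"
"SUDDEN DEATH","SUDDEN DEATH"
"COMPLETED SUICIDE","SUICIDAL BEHAVIOUR"
"SUICIDAL BEHAVIOUR","SUICIDAL BEHAVIOUR"
"SUICIDAL IDEATION","SUICIDAL BEHAVIOUR"
"SUICIDE ATTEMPT","SUICIDAL BEHAVIOUR"
"ATRIAL FIBRILLATION","SUPRAVENTRICULAR TACHYCARDIA"
"SUPRAVENTRICULAR TACHYCARDIA","SUPRAVENTRICULAR TACHYCARDIA"
"TACHYCARDIA","TACHYCARDIA"
"THROMBOCYTOPENIA","THROMBOCYTOPENIA"
"THROMBOPHLEBITIS","THROMBOPHLEBITIS"
"THROMBOSIS","THROMBOSIS"
"TINNITUS","TINNITUS"
"TOXIC EPIDERMAL NECROLYSIS","TOXIC EPIDERMAL NECROLYSIS"
"ULCER","ULCER"
"UPPER RESPIRATORY TRACT INFECTION","UPPER RESPIRATORY TRACT INFECTION"
"URINARY TRACT INFECTION","URINARY TRACT INFECTION"
"URTICARIA","URTICARIA"
"VAGINAL HAEMORRHAGE","VAGINAL HAEMORRHAGE"
"VASCULITIS","VASCULITIS"
"VENTRICULAR ARRHYTHMIA","VENTRICULAR ARRHYTHMIA"
"VENTRICULAR EXTRASYSTOLES","VENTRICULAR ARRHYTHMIA"
"VENTRICULAR FIBRILLATION","VENTRICULAR ARRHYTHMIA"
"VENTRICULAR TACHYCARDIA","VENTRICULAR ARRHYTHMIA"
"VISION BLURRED","VISION BLURRED"
"VISUAL ACUITY REDUCED","VISUAL IMPAIRMENT"
"VISUAL FIELD DEFECT","VISUAL IMPAIRMENT"
"VISUAL IMPAIRMENT","VISUAL IMPAIRMENT"
"WEIGHT INCREASED","WEIGHT INCREASED"
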