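code,dialect,condition_label,human_name
H3...,PRESCRIPTION_UK_LIKE,COPD,chronic obstructive pulmonary disease
H32..,PRESCRIPTION_UK_LIKE,COPD,emphysema
C370.,PRESCRIPTION_UK_LIKE,CYSTIC_FIBROSIS,cystic fibrosis
C3701,PRESCRIPTION_UK_LIKE,CYSTIC_FIBROSIS,cystic fibrosis with pulmonary manifestations
B22..,PRESCRIPTION_UK_LIKE,LUNG_CANCER,malignant neoplasm of bronchus and lung
B221.,PRESCRIPTION_UK_LIKE,LUNG_CANCER,malignant neoplasm of main bronchus
H34..,PRESCRIPTION_UK_LIKE,BRONCHIECTASIS,bronchiectasis
H340.,PRESCRIPTION_UK_LIKE,BRONCHIECTASIS,recurrent bronchiectasis
A1...,PRESCRIPTION_UK_LIKE,TUBERCULOSIS,respiratory tuberculosis
A11..,PRESCRIPTION_UK_LIKE,TUBERCULOSIS,pulmonary tuberculosis
D862.,PRESCRIPTION_UK_LIKE,SARCOIDOSIS,sarcoidosis of lung
D863.,PRESCRIPTION_UK_LIKE,SARCOIDOSIS,sarcoidosis of lymph nodes
H33..,PRESCRIPTION_UK_LIKE,ASTHMA,asthma
H330.,PRESCRIPTION_UK_LIKE,ASTHMA,extrinsic atopic asthma
Z00..,PRESCRIPTION_UK_LIKE,OTHER,general examination
J44,DISPENSATION_FR_LIKE,COPD,chronic obstructive pulmonary disease
J44.9,DISPENSATION_FR_LIKE,COPD,COPD unspecified
E84,DISPENSATION_FR_LIKE,CYSTIC_FIBROSIS,cystic fibrosis
E84.0,DISPENSATION_FR_LIKE,CYSTIC_FIBROSIS,cystic fibrosis with pulmonary manifestations
C34,DISPENSATION_FR_LIKE,LUNG_CANCER,malignant neoplasm of bronchus and lung
C34.9,DISPENSATION_FR_LIKE,LUNG_CANCER,lung cancer unspecified
J47,DISPENSATION_FR_LIKE,BRONCHIECTASIS,bronchiectasis
J47.9,DISPENSATION_FR_LIKE,BRONCHIECTASIS,bronchiectasis unspecified
A15,DISPENSATION_FR_LIKE,TUBERCULOSIS,respiratory tuberculosis bacteriologically confirmed
A16,DISPENSATION_FR_LIKE,TUBERCULOSIS,respiratory tuberculosis not confirmed
D86,DISPENSATION_FR_LIKE,SARCOIDOSIS,sarcoidosis
D86.0,DISPENSATION_FR_LIKE,SARCOIDOSIS,sarcoidosis of lung
J45,DISPENSATION_FR_LIKE,ASTHMA,asthma
J45.9,DISPENSATION_FR_LIKE,ASTHMA,asthma unspecified
Z00,DISPENSATION_FR_LIKE,OTHER,general examination
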