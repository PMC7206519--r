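# Default severity ruleset for the 33-term education space.
# Grading convention: value 1/2/3 rules for one field share a priority and
# the maximum matching value wins, so each rule only states its lower bound.
# Lab bands grade by fold over the reference limit: within 1.2x -> 1,
# within 1.5x -> 2, beyond -> 3 (symmetric below the lower limit).
# All cut-points here are configuration and may be overridden.

# --- blood pressure (mm Hg); normal below 140/90 ---
- {term: blood_pressure, when: 'systolic_bp >= 140 | diastolic_bp >= 90', value: 1}
- {term: blood_pressure, when: 'systolic_bp >= 160 | diastolic_bp >= 100', value: 2}
- {term: blood_pressure, when: 'systolic_bp >= 180 | diastolic_bp >= 110', value: 3}

# --- blood glucose (mmol/L); reference 3.9-6.1 ---
- {term: blood_glucose, when: 'glucose > 6.1 | glucose < 3.9', value: 1}
- {term: blood_glucose, when: 'glucose > 7.32 | glucose < 3.25', value: 2}
- {term: blood_glucose, when: 'glucose > 9.15 | glucose < 2.6', value: 3}

# --- total cholesterol (mmol/L); reference 2.9-5.2 ---
- {term: total_cholesterol, when: 'total_cholesterol > 5.2 | total_cholesterol < 2.9', value: 1}
- {term: total_cholesterol, when: 'total_cholesterol > 6.24 | total_cholesterol < 2.4167', value: 2}
- {term: total_cholesterol, when: 'total_cholesterol > 7.8 | total_cholesterol < 1.9333', value: 3}

# --- triglyceride (mmol/L); reference 0.56-1.70 ---
- {term: triglyceride, when: 'triglyceride > 1.7 | triglyceride < 0.56', value: 1}
- {term: triglyceride, when: 'triglyceride > 2.04 | triglyceride < 0.4667', value: 2}
- {term: triglyceride, when: 'triglyceride > 2.55 | triglyceride < 0.3733', value: 3}

# --- HDL (mmol/L); reference 1.20-1.68 ---
- {term: hdl, when: 'hdl > 1.68 | hdl < 1.2', value: 1}
- {term: hdl, when: 'hdl > 2.016 | hdl < 1.0', value: 2}
- {term: hdl, when: 'hdl > 2.52 | hdl < 0.8', value: 3}

# --- LDL (mmol/L); reference 2.07-3.12 ---
- {term: ldl, when: 'ldl > 3.12 | ldl < 2.07', value: 1}
- {term: ldl, when: 'ldl > 3.744 | ldl < 1.725', value: 2}
- {term: ldl, when: 'ldl > 4.68 | ldl < 1.38', value: 3}

# --- uric acid (umol/L); sex- and age-specific reference ranges ---
- {term: uric_acid, when: 'sex == "male" & age < 60 & (uric_acid > 416 | uric_acid < 149)', value: 1}
- {term: uric_acid, when: 'sex == "male" & age < 60 & (uric_acid > 499.2 | uric_acid < 124.17)', value: 2}
- {term: uric_acid, when: 'sex == "male" & age < 60 & (uric_acid > 624 | uric_acid < 99.33)', value: 3}
- {term: uric_acid, when: 'sex == "female" & age < 60 & (uric_acid > 357 | uric_acid < 89)', value: 1}
- {term: uric_acid, when: 'sex == "female" & age < 60 & (uric_acid > 428.4 | uric_acid < 74.17)', value: 2}
- {term: uric_acid, when: 'sex == "female" & age < 60 & (uric_acid > 535.5 | uric_acid < 59.33)', value: 3}
- {term: uric_acid, when: 'sex == "male" & age >= 60 & (uric_acid > 476 | uric_acid < 250)', value: 1}
- {term: uric_acid, when: 'sex == "male" & age >= 60 & (uric_acid > 571.2 | uric_acid < 208.33)', value: 2}
- {term: uric_acid, when: 'sex == "male" & age >= 60 & (uric_acid > 714 | uric_acid < 166.67)', value: 3}
- {term: uric_acid, when: 'sex == "female" & age >= 60 & (uric_acid > 434 | uric_acid < 190)', value: 1}
- {term: uric_acid, when: 'sex == "female" & age >= 60 & (uric_acid > 520.8 | uric_acid < 158.33)', value: 2}
- {term: uric_acid, when: 'sex == "female" & age >= 60 & (uric_acid > 651 | uric_acid < 126.67)', value: 3}

# --- BMI (kg/m^2); Chinese reference range 18.5-23.9 ---
- {term: bmi, when: 'bmi >= 24 | bmi < 18.5', value: 1}
- {term: bmi, when: 'bmi >= 28 | bmi < 17', value: 2}
- {term: bmi, when: 'bmi >= 32 | bmi < 16', value: 3}
- {term: obesity, when: 'bmi >= 28', value: 2}

# --- questionnaires ---
- {term: depression, when: 'phq9 >= 5', value: 1}
- {term: depression, when: 'phq9 >= 10', value: 2}
- {term: depression, when: 'phq9 >= 15', value: 3}
- {term: physical_activity, when: 'ipaq == "moderate"', value: 1}
- {term: physical_activity, when: 'ipaq == "low"', value: 2}

# --- lifestyle self-monitoring ---
- {term: diet, when: 'diet == "medium"', value: 1}
- {term: diet, when: 'diet == "poor"', value: 2}
- {term: salt_intake, when: 'diet == "poor"', value: 1}
- {term: smoking, when: 'cigarettes_per_day >= 1', value: 1}
- {term: smoking, when: 'cigarettes_per_day >= 10', value: 2}
- {term: smoking, when: 'cigarettes_per_day >= 20', value: 3}
- {term: drinking, when: 'drinks_per_week >= 1', value: 1}
- {term: drinking, when: 'drinks_per_week >= 8', value: 2}
- {term: drinking, when: 'drinks_per_week >= 15', value: 3}

# --- disease history: a recorded diagnosis signals need for that topic ---
- {term: hypertension, when: '"hypertension" %in% disease_history', value: 2}
- {term: diabetes, when: '"diabetes" %in% disease_history', value: 2}
- {term: stroke, when: '"stroke" %in% disease_history', value: 2}
- {term: hyperlipidemia, when: '"hyperlipidemia" %in% disease_history', value: 2}
- {term: coronary_artery_disease, when: '"coronary_artery_disease" %in% disease_history', value: 2}
- {term: copd, when: '"copd" %in% disease_history', value: 2}
- {term: kidney_disease, when: '"kidney_disease" %in% disease_history', value: 2}
- {term: heart_failure, when: '"heart_failure" %in% disease_history', value: 2}

# --- medication: a current prescription signals relevance of drug education ---
- {term: antihypertensive_drug, when: '"antihypertensive" %in% medications', value: 1}
- {term: hypoglycemic_drug, when: '"hypoglycemic" %in% medications', value: 1}
- {term: hypolipidemic_drug, when: '"hypolipidemic" %in% medications', value: 1}
- {term: medication_adherence, when: 'medication_adherence == "medium"', value: 1}
- {term: medication_adherence, when: 'medication_adherence == "poor"', value: 2}

# --- demographics ---
- {term: pregnancy, when: 'pregnant', value: 2}
- {term: male, when: 'sex == "male"', value: 0}
- {term: female, when: 'sex == "female"', value: 0}
- {term: age, when: 'age >= 0', value: 0}

# --- profile terms with no default severity contribution ---
- {term: sleep, when: 'TRUE', value: 0}
- {term: self_monitoring, when: 'TRUE', value: 0}
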