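term_id,term_label,gbd_category
D003920,Diabetes Mellitus,Diabetes and kidney diseases
D003924,"Diabetes Mellitus, Type 2",Diabetes and kidney diseases
D009203,Myocardial Ischemia,Cardiovascular diseases
D003327,Coronary Disease,Cardiovascular diseases
D020521,Stroke,Cardiovascular diseases
D001714,Bipolar Disorder,Mental disorders
D003863,Depression,Mental disorders
D009369,Neoplasms,Neoplasms
D001943,Breast Neoplasms,Neoplasms
D014376,Tuberculosis,Respiratory infections and tuberculosis
D011014,Pneumonia,Respiratory infections and tuberculosis
D003967,Diarrhea,Enteric infections
D012141,Respiratory Tract Infections,Respiratory infections and tuberculosis
D001249,Asthma,Chronic respiratory diseases
D029424,Chronic Obstructive Pulmonary Disease,Chronic respiratory diseases
D015658,HIV Infections,HIV/AIDS and sexually transmitted infections
D008288,Malaria,Neglected tropical diseases and malaria
D009140,Musculoskeletal Diseases,Musculoskeletal disorders
D004827,Epilepsy,Neurological disorders
D000544,Alzheimer Disease,Neurological disorders
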