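site,arm,n_patients,component,value,currency
Ulm,imaging,107,practitioner_visits,69771.40,EUR
Ulm,imaging,107,patient_assessments,29228.00,EUR
Ulm,imaging,107,mri,36219.00,EUR
Ulm,imaging,107,mpmri,23177.00,EUR
Ulm,soc,109,practitioner_visits,78365.20,EUR
Ulm,soc,109,patient_assessments,38183.70,EUR
Leiden,imaging,89,practitioner_visits,133499.00,EUR
Leiden,imaging,89,patient_assessments,18722.95,EUR
Leiden,imaging,89,mri,35798.00,EUR
Leiden,imaging,89,mpmri,25284.00,EUR
Leiden,soc,88,practitioner_visits,115944.00,EUR
Leiden,soc,88,patient_assessments,14236.30,EUR
Coimbra,imaging,79,practitioner_visits,3676.90,EUR
Coimbra,imaging,79,patient_assessments,863.10,EUR
Coimbra,imaging,79,mri,7290.00,EUR
Coimbra,imaging,79,mpmri,17460.00,EUR
Coimbra,soc,75,practitioner_visits,3455.10,EUR
Coimbra,soc,75,patient_assessments,1102.00,EUR
UK,imaging,128,practitioner_visits,56550.00,GBP
UK,imaging,128,patient_assessments,3435.00,GBP
UK,imaging,128,mri,15210.00,GBP
UK,imaging,128,mpmri,30186.00,GBP
UK,soc,127,practitioner_visits,62463.00,GBP
UK,soc,127,patient_assessments,6181.00,GBP
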