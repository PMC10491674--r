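category,raw_term,controlled_term
absolute_body_weight,decrease,body weight decreased
absolute_body_weight,decreased body weight,body weight decreased
absolute_body_weight,increase,body weight increased
absolute_body_weight,lower body weight,body weight decreased
body_weight_gain,decrease,body weight gain decreased
body_weight_gain,reduced gain,body weight gain decreased
body_weight_gain,increase,body weight gain increased
macroscopic,decrease in size,decreased size
macroscopic,small size,decreased size
macroscopic,enlargement,enlarged
macroscopic,discoloration,discoloration
macroscopic,dark focus,discoloration
macroscopic,thickening,thickened
macroscopic,mass,mass
microscopic,hepatocyte hypertrophy,hepatocellular hypertrophy
microscopic,hepatocellular hypertrophy,hepatocellular hypertrophy
microscopic,hypertrophy,hypertrophy
microscopic,atrophy,atrophy
microscopic,lymphoid depletion,lymphoid cellularity decreased
microscopic,decreased cellularity,cellularity decreased
microscopic,single cell necrosis,necrosis
microscopic,necrosis,necrosis
microscopic,vacuolation,vacuolation
microscopic,inflammatory cell infiltrate,mononuclear cell infiltration
microscopic,mononuclear cell infiltration,mononuclear cell infiltration
microscopic,fibrosis,fibrosis
microscopic,mineralization,mineralization
microscopic,axonal degeneration,axonal degeneration
microscopic,degeneration,degeneration
microscopic,hyperplasia,hyperplasia
microscopic,pigment deposition,pigmentation
organ_weights,decrease,organ weight decreased
organ_weights,decreased weight,organ weight decreased
organ_weights,increase,organ weight increased
organ_weights,increased weight,organ weight increased
cardiovascular,increased heart rate,heart rate increased
cardiovascular,heart rate increase,heart rate increased
cardiovascular,decreased heart rate,heart rate decreased
cardiovascular,qtc prolongation,QTc interval prolonged
cardiovascular,blood pressure decrease,blood pressure decreased
neurological_clinical_signs,tremors,tremor
neurological_clinical_signs,tremor,tremor
neurological_clinical_signs,hypoactivity,hypoactivity
neurological_clinical_signs,convulsions,convulsion
neurological_clinical_signs,ataxia,ataxia
neurological_clinical_signs,uncoordinated gait,ataxia
git_clinical_signs,salivation,salivation
git_clinical_signs,vomit,emesis
git_clinical_signs,vomiting,emesis
git_clinical_signs,emesis,emesis
git_clinical_signs,diarrhea,diarrhea
git_clinical_signs,soft feces,soft feces
git_clinical_signs,reduced food consumption,food consumption decreased
other_clinical_signs,irregular respiration,respiration irregular
other_clinical_signs,piloerection,piloerection
other_clinical_signs,hunched posture,hunched posture
other_clinical_signs,swelling,swelling
other_clinical_signs,hair loss,alopecia
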