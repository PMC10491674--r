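finding,species_group,scope,tp,fp,fn,tn,plus_lr_printed,inv_neg_lr_printed,p_printed
eye_conjunctiva,non_rodent,non_adverse,2,0,3,37,Inf,1.67,0.01
muscular_skeletal_system,non_rodent,non_adverse,2,0,3,37,Inf,1.67,0.01
nervous_system,non_rodent,non_adverse,2,1,1,38,26,2.92,0.01
cutaneous,non_rodent,non_adverse,10,2,3,27,11.15,4.03,0
neurological_clinical_signs,non_rodent,non_adverse,6,3,2,31,8.5,3.65,0
git_clinical_signs,non_rodent,non_adverse,10,3,2,27,8.33,5.4,0
liver,non_rodent,non_adverse,7,5,1,29,5.95,6.82,0
cardiovascular,non_rodent,non_adverse,3,5,1,33,5.7,3.47,0.02
urinary_system,non_rodent,non_adverse,3,4,2,33,5.55,2.23,0.03
body_weight_changes,non_rodent,non_adverse,14,7,0,21,4,Inf,0
lymphoid_tissues,non_rodent,non_adverse,8,7,2,25,3.66,3.91,0
other_clinical_signs,non_rodent,non_adverse,7,4,8,23,3.15,1.6,0.03
nervous_system,non_rodent,adverse,2,0,0,40,Inf,Inf,0
lymphoid_tissues,non_rodent,adverse,2,1,0,39,40,Inf,0
liver,non_rodent,adverse,2,1,1,38,26,2.92,0.01
neurological_clinical_signs,non_rodent,adverse,3,2,2,35,11.1,2.36,0.01
body_weight_changes,non_rodent,adverse,2,5,0,35,8,Inf,0.02
reproductive_system,rodent,non_adverse,4,1,2,23,16,2.87,0
git_clinical_signs,rodent,non_adverse,7,2,2,19,8.17,4.07,0
gi_tract,rodent,non_adverse,5,2,4,19,5.83,2.04,0.01
cutaneous,rodent,non_adverse,5,3,3,19,4.58,2.3,0.02
endocrine_system,rodent,non_adverse,13,4,1,12,3.71,10.5,0
liver,rodent,non_adverse,14,4,2,10,3.06,5.71,0
lymphoid_tissues,rodent,non_adverse,9,5,4,12,2.35,2.29,0.04
body_weight_changes,rodent,non_adverse,14,4,4,8,2.33,3,0.02
liver,rodent,adverse,3,0,1,26,Inf,4,0
lymphoid_tissues,rodent,adverse,2,2,1,25,9,2.78,0.04
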