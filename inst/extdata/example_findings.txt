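study_id	category	raw_term	organ	adverse	onset_dose_per_day	severity	reversibility	notes
ST-001	microscopic	hepatocyte hypertrophy	liver	no	50	minimal	reversible	
ST-002	microscopic	Hepatocyte hypertrophy	liver	yes	50	moderate	reversible	
ST-002	organ_weights	increase	liver	no	15			
ST-003	microscopic	hepatocellular hypertrophy	liver	yes	50	moderate	not reversible	
ST-003	neurological_clinical_signs	tremors		yes	50	mild	reversible	
ST-004	git_clinical_signs	vomit		no	15			secondary to dosing procedure
ST-005	git_clinical_signs	emesis		no	15			
ST-006	absolute_body_weight	decrease		no	100			
ST-007	microscopic	lymphoid depletion	thymus gland	no	100	minimal	reversible	
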