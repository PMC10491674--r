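study_id	molecule_id	modality	species	duration_weeks	therapeutic_area	route	dose_levels	administrations_per_day	noael_dose_per_day	dose_units
ST-001	MOL-A	small	rat	4	neurosciences	oral gavage	5;15;50	1	50	mg/kg/day
ST-002	MOL-A	small	rat	13	neurosciences	oral gavage	5;15;50	1	15	mg/kg/day
ST-003	MOL-A	small	rat	26	neurosciences	oral gavage	5;15;50	1	15	mg/kg/day
ST-004	MOL-A	small	cynomolgus monkey	4	neurosciences	oral gavage	2.5;7.5;25	2	15	mg/kg/day
ST-005	MOL-A	small	cynomolgus monkey	39	neurosciences	oral gavage	5;15;50	1	not identified	mg/kg/day
ST-006	MOL-B	large	cynomolgus monkey	4	oncology	intravenous	10;30;100	1	100	mg/kg/day
ST-007	MOL-B	large	cynomolgus monkey	26	oncology	intravenous	10;30;100	1	100	mg/kg/day
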