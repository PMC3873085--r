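variable	case_count	control_count
total	19356	96780
male	5328	26640
followup_index_disease	3664	0
age_le50	13530	67650
age_b51_64	3724	18620
age_ge65	2102	10510
amitriptyline_user	211	335
flunarizine_user	2533	2406
propranolol_user	6626	10011
topiramate_user	428	96
valproic_acid_user	113	136
ergotamine_user	6088	2575
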