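drug	mg_per_ddd
amitriptyline	75
flunarizine	10
propranolol	160
topiramate	300
valproic_acid	1500
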