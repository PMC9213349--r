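name	targets	delta_mass	nterm_only
carbamidomethyl	C	57.02146	FALSE
oxidation	M,P,W,Y,C,K	15.99491	FALSE
dioxidation	W,Y,M	31.98983	FALSE
trioxidation	C	47.98474	FALSE
deamidation	N,Q	0.98402	FALSE
pyro_glu_q	Q	-17.02655	TRUE
pyro_glu_e	E	-18.01056	TRUE
acetyl	K	42.01057	FALSE
kynurenine	W	3.99491	FALSE
iodination	Y	125.89664	FALSE
diiodination	Y	251.79328	FALSE
oxolactone	W	13.97926	FALSE
dopaquinone	Y	13.97926	FALSE
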