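peptide	chain	charge	mz	printed_mass	n_hydroxyproline	reference_trait
GNDGATGAAGPPGPTGPAGPPGFPGAVGAK	col1a1	3	850.4013	2548.1802	NA	G3SSE0_162_192
VGPPGPSGNAGPPGPPGPAGKEGAK	col1a1	3	738.6978	2213.0697	4	G3SSE0_723_747
GPPGSAGTPGKDGLNGLPGPIGPPGPR	col1a1	3	828.8729	2483.595	NA	G3SSE0_982_1008
GSDGEAGSAGPAGPPGLR	col1a2	2	784.8686	1567.7214	1	G3TIC0_303_320
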