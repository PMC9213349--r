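>G3SSE0_162_192 offset=162 Loxodonta africana col1a1 tryptic trait Gly162-Lys192 (mature-chain numbering)
GNDGATGAAGPPVSPTGPAGPPGFPGAVGAK
>G3SSE0_723_747 offset=723 Loxodonta africana col1a1 tryptic trait Val723-Lys747
VGPPGPSGNAGPPGPPGPAGKEGGK
>G3SSE0_982_1008 offset=982 Loxodonta africana col1a1 tryptic trait Gly982-Arg1008
GPPGSAGAPGKDGLNGLPGPIGPPGPR
>G3SSE0_393_414 offset=393 Loxodonta africana col1a1 tryptic trait Thr393-Arg414 (entry lacks Gly400)
TGPPGPAGQDGRPGPPGPPGAR
>G3TIC0_303_320 offset=303 Loxodonta africana col1a2 tryptic trait Gly303-Arg320
GSSGEAGSAGPAGPPGLR
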