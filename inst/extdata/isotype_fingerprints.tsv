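species	kind	label	peptide
human	anchor	FR4	VTVSS
human	fingerprint	M	GSASAPT
human	fingerprint	D	APTKAP
human	fingerprint	G	ASTKGPS
human	fingerprint	A	ASPTSP
human	fingerprint	A1	ASPTSPKVFPLSLCSTQP
human	fingerprint	A2	ASPTSPKVFPLSLDSTPQ
human	fingerprint	E	ASTQSP
mouse	anchor	FR4	VTVSS
mouse	anchor	FR4	LTVSS
mouse	anchor	FR4	VTVSA
mouse	fingerprint	M	ESQSFP
mouse	fingerprint	D	GDKKEP
mouse	fingerprint	G	AKTTAP
mouse	fingerprint	G	AKTTPP
mouse	fingerprint	A	ESARNP
mouse	fingerprint	E	ASIRNP
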