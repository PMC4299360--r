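a1_development	ftp	no_ftp
balanced	295	1317
mild_variation	70	263
hypoplasia	41	165
absent	32	63
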