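a1_segment	normal	I	II	III	IV
normal	576	8	16	13	21
mild_variation	281	5	20	23	4
hypoplasia	172	1	15	16	2
absent	73	2	7	12	1
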