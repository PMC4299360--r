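shape	normal	double_branch	y_pattern	window_pattern	ampulla	circle_pattern	absence	not_clear
cases	1631	76	22	88	14	3	383	29
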