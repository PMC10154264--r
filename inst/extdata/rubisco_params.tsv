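temperature_C	kcatC_s	KCair_uM	source
10	0.9	22	measured
18	1.830	36.3	interpolated
25	3.3	55	measured
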