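subject_id	group	voc_id	name	cas	retention_time_min	mz	fragment_area	tic_area
s1	positive	dms	Dimethyl sulfone	67-71-0	33.89	79	1450200	4350600
s1	positive	dms	Dimethyl sulfone	67-71-0	33.89	94	797610	4350600
s1	positive	hexanoic_acid	Hexanoic acid	142-62-1	32.89	60	281400	844200
s2	control	dms	Dimethyl sulfone	67-71-0	33.89	79	640300	1920900
s2	control	dms	Dimethyl sulfone	67-71-0	33.89	94	352165	1920900
s2	control	hexanoic_acid	Hexanoic acid	142-62-1	32.89	60	430800	1292400
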