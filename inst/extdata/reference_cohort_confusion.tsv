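patient	tp	tn	fp	fn
Pt1	14	55	0	1
Pt2	13	39	6	0
Pt3	8	42	1	3
Pt4	14	33	3	1
Pt5	3	29	0	1
Pt6	14	27	7	0
Pt7	14	36	4	0
Pt8	10	15	3	2
Pt9	6	24	2	2
Pt10	14	19	4	0
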