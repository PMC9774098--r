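patient	n_soz	n_nsoz
Pt1	15	55
Pt2	13	45
Pt3	11	43
Pt4	15	36
Pt5	4	29
Pt6	14	34
Pt7	14	40
Pt8	12	18
Pt9	8	26
Pt10	14	23
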