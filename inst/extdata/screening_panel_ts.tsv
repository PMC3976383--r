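status	hom_ins	het	hom_wt
case	22	2	11
obligate_carrier	0	9	7
control	0	8	92
unknown	2	22	72
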