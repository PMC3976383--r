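status	hom_ins	het	hom_wt
case	4	1	7
control	0	0	10
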