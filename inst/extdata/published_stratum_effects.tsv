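label	stratum	or	ci_low	ci_high	p_het_printed
rs731236	low	0.94	0.78	1.14	0.009
rs731236	high	1.31	1.11	1.55	0.009
rs7975232	low	0.98	0.83	1.16	0.006
rs7975232	high	1.38	1.17	1.62	0.006
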