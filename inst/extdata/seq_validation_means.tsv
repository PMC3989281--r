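gene	mean_ivv	mean_ivm	seq_p	rq_ivv	rq_ivv_se	rq_ivm	rq_ivm_se	qpcr_p
ATG4	7.8	17.0	NS	3.2	0.5	3.3	0.5	NS
HSP90AA1	4.5	13.9	NS	7.7	0.6	5.8	0.6	<0.06
MRPS36	43.7	23.8	NS	3.85	0.4	0.7	0.4	<0.001
PDHX	99.8	69.1	NS	7.9	1.1	4.2	1.1	<0.03
SLC7A3	15.7	43.6	<0.02	1.8	0.4	3.6	0.5	<0.02
SOX4	62.2	21.6	<0.06	4.7	0.2	4.2	0.2	NS
UBAP2	26.5	86.0	NS	5.3	0.5	3.8	0.6	<0.09
ZP2	141.2	1134.2	<0.06	84.1	16.8	272.0	16.8	<0.001
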