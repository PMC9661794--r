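type	D_officinale	D_chrysotoxum	D_nobile	P_equestris	V_planifolia	A_shenzhenica	A_thaliana
CNL	10	14	18	7	2	4	40
CNLCN	1	1	0	0	0	0	0
CNNL	0	0	0	1	0	0	0
NL	9	9	14	3	2	3	18
NLNL	1	0	0	0	0	0	0
NLNNL	1	0	0	0	0	0	0
NNL	0	1	0	0	0	0	0
TNL	0	0	0	0	0	0	48
TNLC	0	0	0	0	0	0	1
TNLT	0	0	0	0	0	0	4
TNNL	0	0	0	0	0	0	1
NLT	0	0	0	0	0	0	2
CN	24	30	57	18	6	3	40
CNC	1	0	0	0	0	0	0
CNCN	0	0	3	1	0	0	0
N	27	58	75	21	1	4	22
NN	0	2	1	0	0	0	0
NNN	0	1	0	0	0	0	0
NC	0	0	0	6	0	0	0
NNC	0	1	0	0	0	0	0
TN	0	0	0	0	0	0	31
TNN	0	0	0	0	0	0	2
TNC	0	1	1	0	1	1	0
RN	0	0	0	0	0	0	1
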