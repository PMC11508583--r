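alias	canonical
COI	COX1
CO1	COX1
COXI	COX1
COX1	COX1
MT-CO1	COX1
COII	COX2
CO2	COX2
COXII	COX2
COX2	COX2
MT-CO2	COX2
COIII	COX3
CO3	COX3
COXIII	COX3
COX3	COX3
MT-CO3	COX3
COB	CYTB
CYB	CYTB
CYTB	CYTB
MT-CYB	CYTB
NAD1	ND1
NADH1	ND1
ND1	ND1
NAD2	ND2
NADH2	ND2
ND2	ND2
NAD3	ND3
NADH3	ND3
ND3	ND3
NAD4	ND4
NADH4	ND4
ND4	ND4
NAD4L	ND4L
NADH4L	ND4L
ND4L	ND4L
NAD5	ND5
NADH5	ND5
ND5	ND5
NAD6	ND6
NADH6	ND6
ND6	ND6
ATP6	ATP6
ATPASE6	ATP6
ATP8	ATP8
ATPASE8	ATP8
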