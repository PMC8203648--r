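	Am	BFB	BNST	Bs	CE	Cer	CPu	cxAss	cxCg	cxIns	cxM	cxS1	cxS2	Hc	Hy	lTh	mTh	PAG
Am	0	1	1	1	0	0	1	0	0	1	0	0	0	1	1	0	1	1
BFB	1	0	1	1	1	0	1	1	1	0	0	0	0	1	1	0	1	0
BNST	1	1	0	1	1	0	0	0	0	0	0	0	0	0	1	0	0	1
Bs	1	1	1	0	1	1	0	0	0	0	0	1	1	0	1	1	1	1
CE	1	1	1	1	0	0	0	0	0	1	0	0	0	0	1	0	1	1
Cer	0	0	0	1	0	0	0	0	0	0	1	0	0	0	0	1	0	0
CPu	0	1	0	1	0	0	0	0	0	0	1	0	0	0	0	1	1	0
cxAss	0	1	0	0	0	0	1	0	1	1	1	1	1	1	0	1	1	0
cxCg	0	1	0	0	0	0	1	1	0	1	1	1	0	1	0	1	1	1
cxIns	1	0	0	1	1	0	1	1	1	0	1	1	1	0	1	1	1	0
cxM	0	0	0	1	0	1	1	1	1	1	0	1	1	0	0	1	1	0
cxS1	0	0	0	1	0	0	1	1	1	1	1	0	1	0	0	1	1	0
cxS2	0	0	0	1	0	0	1	1	0	1	1	1	0	0	0	1	1	0
Hc	1	1	1	1	0	0	0	1	1	0	0	0	0	0	1	1	1	0
Hy	1	1	1	1	1	0	0	0	0	0	0	0	0	1	0	0	1	1
lTh	0	0	0	1	0	1	1	1	1	1	1	1	1	1	0	0	0	1
mTh	1	1	0	1	1	0	1	1	1	1	1	1	1	1	1	0	0	1
PAG	1	0	1	1	1	0	0	0	0	0	0	0	0	0	1	1	1	0
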