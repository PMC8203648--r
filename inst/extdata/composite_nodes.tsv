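abbrev	name
Am	amygdala
BFB	basal forebrain including septum, diagonal band of Broca, nucleus accumbens, pallidum
BNST	bed nucleus of stria terminalis
Bs	brainstem
CE	central amygdala
Cer	cerebellum
CPu	caudate putamen
cxAss	parts of association cortex
cxCg	cingulate cortex
cxIns	insular cortex
cxM	motor cortex
cxS1	primary somatosensory cortex
cxS2	secondary somatosensory cortex
Hc	hippocampus
Hy	hypothalamus
lTh	lateral thalamus
mTh	medial thalamus
PAG	periaqueductal gray
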