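node_a	node_b	t_stat
Inferior frontal gyrus (pars opercularis) right	Superior frontal gyrus (medial) left	5.02
Inferior frontal gyrus (pars opercularis) right	Superior frontal gyrus (dorsal) left	4.08
Orbitofrontal cortex (medial) left	Orbitofrontal cortex (medial) right	3.7
Inferior frontal gyrus (pars opercularis) right	Inferior frontal gyrus (pars opercularis) left	3.69
Superior frontal gyrus (medial) right	Orbitofrontal cortex (medial) left	3.65
Inferior frontal gyrus (pars opercularis) right	Supplementary motor area left	3.65
Orbitofrontal cortex (medial) right	Rectus gyrus left	3.64
Inferior frontal gyrus (pars triangularis) right	Superior frontal gyrus (medial) left	3.55
Middle frontal gyrus right	Superior frontal gyrus (medial) left	3.52
Superior frontal gyrus (medial) left	Orbitofrontal cortex (medial) right	3.47
Orbitofrontal cortex (middle) right	Posterior cingulate gyrus right	3.36
Orbitofrontal cortex (middle) right	Orbitofrontal cortex (medial) left	3.34
Superior frontal gyrus (medial) left	Superior frontal gyrus (medial) right	3.32
Inferior frontal gyrus (pars opercularis) right	Middle frontal gyrus left	3.3
Inferior frontal gyrus (pars opercularis) right	Orbitofrontal cortex (middle) left	3.26
Orbitofrontal cortex (superior) left	Orbitofrontal cortex (medial) right	3.23
Orbitofrontal cortex (medial) left	Hippocampus right	3.23
Inferior frontal gyrus (pars opercularis) right	Orbitofrontal cortex (medial) left	3.2
Orbitofrontal cortex (superior) right	Superior frontal gyrus (medial) left	3.19
Orbitofrontal cortex (superior) left	Amygdala right	3.16
Orbitofrontal cortex (superior) left	Superior frontal gyrus (medial) right	3.16
Superior frontal gyrus (dorsal) right	Orbitofrontal cortex (medial) left	3.15
Orbitofrontal cortex (superior) right	Orbitofrontal cortex (medial) left	3.13
Inferior frontal gyrus (pars opercularis) right	Orbitofrontal cortex (superior) left	3.13
Middle frontal gyrus left	Orbitofrontal cortex (medial) right	3.11
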