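node_id	region_name	hemisphere	partition_label
Superior frontal gyrus (medial) left	Superior frontal gyrus (medial) left	left	core
Superior frontal gyrus (medial) right	Superior frontal gyrus (medial) right	right	core
Superior frontal gyrus (dorsal) left	Superior frontal gyrus (dorsal) left	left	core
Superior frontal gyrus (dorsal) right	Superior frontal gyrus (dorsal) right	right	core
Middle frontal gyrus left	Middle frontal gyrus left	left	core
Middle frontal gyrus right	Middle frontal gyrus right	right	core
Rectus gyrus left	Rectus gyrus left	left	periphery
Orbitofrontal cortex (medial) left	Orbitofrontal cortex (medial) left	left	periphery
Orbitofrontal cortex (medial) right	Orbitofrontal cortex (medial) right	right	periphery
Orbitofrontal cortex (middle) left	Orbitofrontal cortex (middle) left	left	periphery
Orbitofrontal cortex (middle) right	Orbitofrontal cortex (middle) right	right	periphery
Orbitofrontal cortex (superior) left	Orbitofrontal cortex (superior) left	left	periphery
Orbitofrontal cortex (superior) right	Orbitofrontal cortex (superior) right	right	periphery
Inferior frontal gyrus (pars opercularis) left	Inferior frontal gyrus (pars opercularis) left	left	periphery
Inferior frontal gyrus (pars opercularis) right	Inferior frontal gyrus (pars opercularis) right	right	periphery
Inferior frontal gyrus (pars triangularis) right	Inferior frontal gyrus (pars triangularis) right	right	periphery
Supplementary motor area left	Supplementary motor area left	left	periphery
Posterior cingulate gyrus right	Posterior cingulate gyrus right	right	periphery
Hippocampus right	Hippocampus right	right	periphery
Amygdala right	Amygdala right	right	periphery
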