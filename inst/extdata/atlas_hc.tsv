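name	hemisphere	subfield	division
parasubiculum-L	L	parasubiculum	whole
presubiculum-head-L	L	presubiculum	head
presubiculum-body-L	L	presubiculum	body
subiculum-head-L	L	subiculum	head
subiculum-body-L	L	subiculum	body
CA1-head-L	L	CA1	head
CA1-body-L	L	CA1	body
CA2-3-head-L	L	CA2-3	head
CA2-3-body-L	L	CA2-3	body
CA4-head-L	L	CA4	head
CA4-body-L	L	CA4	body
GC-ML-DG-head-L	L	GC-ML-DG	head
GC-ML-DG-body-L	L	GC-ML-DG	body
molecular-layer-head-L	L	molecular-layer	head
molecular-layer-body-L	L	molecular-layer	body
fimbria-L	L	fimbria	whole
HATA-L	L	HATA	whole
hippocampal-fissure-L	L	hippocampal-fissure	whole
hippocampus-tail-L	L	hippocampus-tail	tail
parasubiculum-R	R	parasubiculum	whole
presubiculum-head-R	R	presubiculum	head
presubiculum-body-R	R	presubiculum	body
subiculum-head-R	R	subiculum	head
subiculum-body-R	R	subiculum	body
CA1-head-R	R	CA1	head
CA1-body-R	R	CA1	body
CA2-3-head-R	R	CA2-3	head
CA2-3-body-R	R	CA2-3	body
CA4-head-R	R	CA4	head
CA4-body-R	R	CA4	body
GC-ML-DG-head-R	R	GC-ML-DG	head
GC-ML-DG-body-R	R	GC-ML-DG	body
molecular-layer-head-R	R	molecular-layer	head
molecular-layer-body-R	R	molecular-layer	body
fimbria-R	R	fimbria	whole
HATA-R	R	HATA	whole
hippocampal-fissure-R	R	hippocampal-fissure	whole
hippocampus-tail-R	R	hippocampus-tail	tail
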