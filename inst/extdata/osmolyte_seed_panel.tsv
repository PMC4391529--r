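seed_id	organism	gene_symbol	pathway
kup	Eco	kup	potassium transport
trkA	Eco	trkA	potassium transport
trkH	Eco	trkH	potassium transport
trkG	Eco	trkG	potassium transport
kdpA	Eco	kdpA	potassium transport
kdpB	Eco	kdpB	potassium transport
kdpC	Eco	kdpC	potassium transport
kdpD	Eco	kdpD	potassium transport
kdpE	Eco	kdpE	potassium transport
kdpF	Eco	kdpF	potassium transport
glnA	Eco	glnA	glutamate synthesis
gltB	Eco	gltB	glutamate synthesis
gltD	Eco	gltD	glutamate synthesis
gdhA	Eco	gdhA	glutamate synthesis
betA	Eco	betA	glycine betaine synthesis
betB	Eco	betB	glycine betaine synthesis
betC	Eco	betC	glycine betaine synthesis
betI	Eco	betI	glycine betaine synthesis
betS	Eco	betS	glycine betaine transport
proP	Eco	proP	glycine betaine, proline and carnitine transport
proV	Eco	proV	glycine betaine, proline and carnitine transport
proW	Eco	proW	glycine betaine, proline and carnitine transport
proZ	Eco	proZ	glycine betaine, proline and carnitine transport
proA	Eco	proA	proline synthesis
proB	Eco	proB	proline synthesis
proC	Eco	proC	proline synthesis
ostA	Eco	ostA	trehalose synthesis
ostB	Eco	ostB	trehalose synthesis
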