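tca_cycle	TCA-cycle-related metabolites	citrate	succinate	glutamate	malate	fumarate
glycolysis	glycolysis end products	glucose	lactate
choline_metabolism	choline-containing compounds	choline	phosphocholine
amino_acids	free amino acids	alanine	glutamine	glutamate	glycine	valine	leucine	isoleucine
osmolytes	osmolytes	myo_inositol	taurine
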