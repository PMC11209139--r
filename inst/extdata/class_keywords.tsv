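class	keyword
toxin_domain	scorpion toxin
toxin_domain	toxin
toxin_domain	defensin
toxin_domain	knottin
toxin_domain	inhibitor cystine knot
peptidase	peptidase
peptidase	protease
peptidase	proteinase
peptidase	trypsin
peptidase	chymotrypsin
peptidase	carboxypeptidase
peptidase	aminopeptidase
peptidase	cathepsin
carboxylesterase	carboxylesterase
carboxylesterase	carboxyl esterase
carboxylesterase	lipase
glycosidase	glycosidase
glycosidase	glucosidase
glycosidase	galactosidase
glycosidase	amylase
glycosidase	glycosyl hydrolase
glycosidase	chitinase
odorant_binding	odorant-binding
odorant_binding	odorant binding
odorant_binding	pheromone-binding
odorant_binding	obp
housekeeping	ribosomal
housekeeping	actin
housekeeping	tubulin
housekeeping	histone
housekeeping	elongation factor
housekeeping	heat shock
housekeeping	atp synthase
housekeeping	cytochrome
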