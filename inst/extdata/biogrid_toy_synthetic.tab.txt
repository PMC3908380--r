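#BioGRID Interaction ID	Official Symbol Interactor A	Official Symbol Interactor B	Experimental System	Experimental System Type	Organism Interactor A	Organism Interactor B
1	InR	chico	Affinity Capture-MS	physical	7227	7227
2	gig	TSC1	Affinity Capture-MS	physical	7227	7227
3	foxo	dm	Synthetic Lethality	genetic	7227	7227
4	chico	InR	Reconstituted Complex	physical	7227	7227
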