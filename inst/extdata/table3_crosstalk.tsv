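compartment	gene_id	description
bud	Gcg	glucagon
bud	Bmp7	bone morphogenetic protein 7
bud	Met	met proto-oncogene
bud	Spp1	secreted phosphoprotein 1
bud	Pcsk9	proprotein convertase subtilisin/kexin type 9
bud	Clu	clusterin
bud	Pyy	peptide YY
bud	Edn3	endothelin 3
bud	Sdc4	syndecan 4
bud	Serpinf2	serine (or cysteine) peptidase inhibitor, clade F, member 2
bud	Pcsk6	proprotein convertase subtilisin/kexin type 6
bud	F5	coagulation factor V
bud	Iapp	islet amyloid polypeptide
bud	Casr	calcium-sensing receptor
bud	Cck	cholecystokinin
bud	Sct	secretin
mesenchyme	Vcan	versican
mesenchyme	Tnc	tenascin C
mesenchyme	Igf1	insulin-like growth factor 1
mesenchyme	Cxcl12	chemokine (C-X-C motif) ligand 12
mesenchyme	Tgfb2	transforming growth factor, beta 2
mesenchyme	Thbs1	thrombospondin 1
mesenchyme	Itga8	integrin alpha 8
mesenchyme	Lpar1	lysophosphatidic acid receptor 1
mesenchyme	Pcsk5	proprotein convertase subtilisin/kexin type 5
mesenchyme	Apob	apolipoprotein B
mesenchyme	Adcyap1r1	adenylate cyclase activating polypeptide 1 receptor 1
mesenchyme	Cxcr4	chemokine (C-X-C motif) receptor 4
mesenchyme	Dcn	decorin
mesenchyme	Thbd	thrombomodulin
mesenchyme	Hgf	hepatocyte growth factor
mesenchyme	Ntsr1	neurotensin receptor 1
mesenchyme	Bmp2	bone morphogenetic protein 2
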