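gene_id	cpm_mean
Peg3	3769.3
Rian	728.7
Nepn	686.2
Ptprf	638.4
Gcg	571.5
Meg3	567.0
Myh9	376.5
Frem2	369.1
Fras1	356.4
Ccnd1	322.5
Prox1	308.0
Spon1	303.3
Cdh1	291.1
Ptpn13	281.9
Slc38a5	275.5
Dlk1	266.3
Chst2	243.9
Adamts1	230.2
Dlg5	229.1
Dsp	225.8
Notch1	214.6
Sox9	210.0
Ankrd50	189.5
Pam	189.4
Aes	188.9
Fryl	187.7
Zim1	167.5
Rap1gap2	167.0
Etl4	161.1
Itga6	159.2
Lama5	157.4
Epcam	155.1
Nav2	154.0
Appl2	153.5
Nr5a2	152.6
Svil	143.9
Parm1	135.8
Itpr3	135.7
Abcc8	135.5
Plk2	129.4
Fbxo21	128.0
Wnk3	127.6
Lrba	120.0
Arg1	119.5
Wnk2	118.5
Jmy	114.6
Cep170b	113.2
Rnf213	111.9
Fndc3b	110.4
Gatsl2	109.5
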