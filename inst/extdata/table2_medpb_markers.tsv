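gene_id	cpm_mean
Mest	589.9
Fbn2	401.2
Zfp462	352.5
Zfhx4	217.0
Sulf2	164.1
Cdh11	157.5
Dpysl3	157.0
Nefm	144.0
Fndc3c1	140.0
Slit2	131.7
Basp1	122.1
Gli3	117.3
Nid1	116.7
Cald1	111.8
Amot	108.9
Msn	105.8
Zeb2	101.9
2810417H13Rik	95.3
Hdgfrp3	92.8
Nhsl2	90.4
Flnc	88.6
Col5a1	88.5
Phactr2	87.8
Hmcn1	86.9
Pcdh18	86.7
Akap12	85.67
Efnb2	83.16
Oxct1	80.50
Epha4	78.03
Zfp423	77.27
Fbn1	75.36
Sacs	75.36
Arhgef40	71.37
Aff3	70.69
Runx1t1	67.79
Lin28b	67.29
Dennd5b	66.06
Cachd1	64.35
Kdr	64.18
Phf6	64.12
Nefl	62.98
Foxp2	62.41
Map1a	60.62
Ets1	60.32
Far1	59.52
Col11a1	55.89
Mmp2	55.79
Cdh5	55.58
Atp11c	55.41
Adam19	55.25
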