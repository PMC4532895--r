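site_type	term	estimate
8mer	(Intercept)	-2.368015
8mer	TA_3UTR	-1.040719
8mer	SPS	-0.123388
8mer	local_AU	-0.320668
8mer	threep_score	-0.043345
8mer	SA	0.089074
8mer	min_dist	0.346705
8mer	P_CT	0
8mer	len_ORF	0.027809
8mer	len_3UTR	0.24453
8mer	off6m	0
8mer	ORF8m	0
8mer	sRNA1_A	0.026094
8mer	sRNA1_C	0.060512
8mer	sRNA1_G	-0.126038
8mer	sRNA8_A	-0.103333
8mer	sRNA8_C	0.094814
8mer	sRNA8_G	0
8mer	site8_A	0
8mer	site8_C	0
8mer	site8_G	0
7mer-m8	(Intercept)	-0.444349
7mer-m8	TA_3UTR	0.01348
7mer-m8	SPS	0.008523
7mer-m8	local_AU	-0.305998
7mer-m8	threep_score	0.013853
7mer-m8	SA	-0.098335
7mer-m8	min_dist	0.360485
7mer-m8	P_CT	0
7mer-m8	len_ORF	-0.004904
7mer-m8	len_3UTR	0.258723
7mer-m8	off6m	0
7mer-m8	ORF8m	0
7mer-m8	sRNA1_A	0.000682
7mer-m8	sRNA1_C	-0.083442
7mer-m8	sRNA1_G	0.025168
7mer-m8	sRNA8_A	0.039291
7mer-m8	sRNA8_C	-0.006792
7mer-m8	sRNA8_G	0
7mer-m8	site8_A	0
7mer-m8	site8_C	0
7mer-m8	site8_G	0
7mer-A1	(Intercept)	-0.632385
7mer-A1	TA_3UTR	-0.234742
7mer-A1	SPS	-0.089727
7mer-A1	local_AU	-0.320277
7mer-A1	threep_score	-0.017453
7mer-A1	SA	0.069652
7mer-A1	min_dist	0.343322
7mer-A1	P_CT	0
7mer-A1	len_ORF	0.147543
7mer-A1	len_3UTR	0.223627
7mer-A1	off6m	0
7mer-A1	ORF8m	-0.019656
7mer-A1	sRNA1_A	0.058642
7mer-A1	sRNA1_C	0.07804
7mer-A1	sRNA1_G	-0.065859
7mer-A1	sRNA8_A	-0.161158
7mer-A1	sRNA8_C	0.013719
7mer-A1	sRNA8_G	0
7mer-A1	site8_A	0.010141
7mer-A1	site8_C	0.087755
7mer-A1	site8_G	0.06011
6mer	(Intercept)	0.952296
6mer	TA_3UTR	0.537762
6mer	SPS	0.032966
6mer	local_AU	-0.380695
6mer	threep_score	0.006529
6mer	SA	0.035722
6mer	min_dist	0.25712
6mer	P_CT	0
6mer	len_ORF	0.033368
6mer	len_3UTR	0.311698
6mer	off6m	0
6mer	ORF8m	0.003115
6mer	sRNA1_A	0.066706
6mer	sRNA1_C	0.04956
6mer	sRNA1_G	0.075418
6mer	sRNA8_A	0.028007
6mer	sRNA8_C	-0.028263
6mer	sRNA8_G	0
6mer	site8_A	0.035349
6mer	site8_C	-0.001749
6mer	site8_G	-0.029709
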