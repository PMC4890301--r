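trait	qtl	chrom	peak_bin	lod_site_a	r2_site_a	additive_site_a	lod_site_b	r2_site_b	additive_site_b
PH	qPH1	1	150	71.9	92.0	45.9	70.9	91.9	39.2
PH	qPH3	3	407	2.6	8.8	21.6	2.8	9.3	19.0
PPL	qPPL1.1	1	40	NA	NA	NA	2.0	6.9	0.7
PPL	qPPL1.2	1	150	NA	NA	NA	10.0	29.9	-0.8
PPL	qPPL2	2	298	NA	NA	NA	2.6	8.7	0.6
PPL	qPPL3	3	317	NA	NA	NA	2.8	9.6	0.8
PPL	qPPL10	10	889	NA	NA	NA	2.5	8.3	0.6
PL	qPL1	1	150	26.6	60.7	2.5	10.6	31.4	1.2
PL	qPL3	3	329	NA	NA	NA	3.8	12.6	-1.7
PL	qPL4	4	456	2.4	8.2	-1.4	2.6	8.9	-0.9
PL	qPL8	8	788	2.5	8.4	1.6	2.4	8.1	1.0
PL	qPL11	11	969	3.1	10.2	2.4	NA	NA	NA
PL	qPL12	12	1059	NA	NA	NA	2.9	9.6	1.1
PBN	qPBN1	1	99	4.0	13.0	-0.6	NA	NA	NA
PBN	qPBN2	2	245	7.7	23.7	-0.9	NA	NA	NA
PBN	qPBN4	4	462	2.9	9.6	-0.6	2.5	8.3	-0.5
PBN	qPBN8	8	781	5.0	16.1	0.7	8.7	26.6	0.9
PBN	qPBN11	11	950	NA	NA	NA	2.3	7.8	1.1
SNPB	qSNPB1	1	29	NA	NA	NA	2.3	7.8	5.9
SNPB	qSNPB2	2	252	4.2	13.6	-5.1	NA	NA	NA
SNPB	qSNPB4.1	4	463	4.0	13.0	-6.5	NA	NA	NA
SNPB	qSNPB4.2	4	470	NA	NA	NA	3.7	12.1	-7.3
SNPB	qSNPB6	6	647	NA	NA	NA	2.1	7.2	-4.5
SNPB	qSNPB7	7	711	4.1	13.3	7.5	4.4	14.3	7.3
SNPB	qSNPB8	8	781	7.5	23.1	7.4	9.3	28.1	7.7
SBN	qSBN1.1	1	15	2.8	9.3	-4.5	2.2	7.6	-3.0
SBN	qSBN1.2	1	149	NA	NA	NA	3.6	12.1	2.4
SBN	qSBN2	2	224	2.5	8.5	-5.2	NA	NA	NA
SBN	qSBN7	7	711	5.8	18.4	-7.7	4.7	15.2	-5.2
SBN	qSBN9	9	817	3.8	12.5	-4.3	3.1	10.5	-2.9
SNSB	qSNSB1.1	1	15	2.9	9.7	-19.1	2.3	7.9	-12.1
SNSB	qSNSB1.2	1	149	NA	NA	NA	2.5	8.4	7.9
SNSB	qSNSB7	7	711	5.5	17.5	-31.1	4.8	15.7	-20.7
SNSB	qSNSB9	9	817	4.8	15.5	-19.8	3.7	12.4	-12.5
SPP	qSPP1.1	1	15	3.2	10.6	-19.6	2.0	6.9	-11.8
SPP	qSPP1.2	1	149	NA	NA	NA	3.0	10.2	9.1
SPP	qSPP2	2	213	2.5	8.3	-18.3	NA	NA	NA
SPP	qSPP7	7	711	3.2	10.5	-23.6	NA	NA	NA
SPP	qSPP9	9	817	4.0	13.1	-17.8	2.1	7.0	-9.8
SS	qSS1	1	150	6.8	22.6	0.1	NA	NA	NA
SS	qSS2	2	298	2.7	9.8	-0.1	NA	NA	NA
SS	qSS3	3	332	2.7	9.6	-0.1	2.5	8.9	-0.04
SS	qSS4	4	492	NA	NA	NA	6.5	22.0	-0.1
SS	qSS6	6	635	NA	NA	NA	3.4	12.1	-0.1
SS	qSS8	8	793	2.6	9.4	-0.04	NA	NA	NA
GL	qGL1.1	1	111	NA	NA	NA	3.5	11.8	0.3
GL	qGL1.2	1	145	4.2	13.9	0.2	NA	NA	NA
GL	qGL3.1	3	373	5.5	17.9	-0.7	6.1	19.9	-0.6
GL	qGL3.2	3	377	5.9	18.9	-0.7	6.2	20.1	-0.6
GL	qGL10	10	896	2.8	9.5	-0.3	NA	NA	NA
GW	qGW2	2	284	NA	NA	NA	5.6	18.5	-0.04
GW	qGW8	8	794	NA	NA	NA	4.5	14.9	-0.1
GW	qGW11.1	11	980	NA	NA	NA	2.9	10.0	-0.04
GW	qGW11.2	11	983	2.3	8.0	-0.1	NA	NA	NA
GW	qGW12	12	1025	NA	NA	NA	3.2	11.0	-0.03
TGW	qTGW1.1	1	38	4.1	16.2	-2.3	2.1	7.5	-1.2
TGW	qTGW1.2	1	148	3.4	13.6	1.1	3.2	11.0	0.9
TGW	qTGW1.3	1	162	NA	NA	NA	3.8	13.0	1.0
TGW	qTGW2	2	310	2.2	9.0	-1.7	5.1	17.2	-1.8
TGW	qTGW3	3	377	2.3	9.7	-2.3	6.5	21.4	-3.0
TGW	qTGW10	10	895	5.3	20.5	-1.8	3.5	12.1	-1.1
YYP	qYYP1	1	149	6.2	23.3	3.5	NA	NA	NA
YYP	qYYP2	2	182	2.1	8.7	4.1	NA	NA	NA
YYP	qYYP4.1	4	494	NA	NA	NA	2.1	7.7	-3.4
YYP	qYYP4.2	4	505	NA	NA	NA	3.1	11.1	7.0
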