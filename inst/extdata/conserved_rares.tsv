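nearest_gene	tad_genes	sequence	motif_type	element_class	conserved_rodent	conserved_human	conserved_bird	conserved_reptile	conserved_frog	conserved_fish	region
C1d	none	GGGTCA G GGGTTA	DR1	enhancer	1	1	1	1	1	1	chr11:18748180-18748192
Clstn1	Lzic, Nmnat1, Kif1b	GGGTCA GA AGGTCA	DR2	enhancer	1	1	1	1	1	0	chr4:149907094-149907107
Dach1	none	AGTTCA CACAA AGTTCA	DR5	enhancer	1	1	1	1	1	1	chr14:98035388-98035404
Dhrs3	none	GGGTCA TTCCA AGTTCA	DR5	enhancer	1	1	1	1	1	0	chr4:145034810-145034826
Dhrs3	none	GGTTCA TCGGG AGGGCA	DR5	enhancer	1	1	1	1	1	0	chr4:145034847-145034863
Foxp4	none	GGGTGA C AGGTCA	DR1	enhancer	1	1	1	1	0	0	chr17:47898625-47898637
Hoxa1	Hoxa4, Hoxa9, Skap2	GGTTCA CCGAA AGTTCA	DR5	enhancer	1	1	1	1	1	0	chr6:52153426-52153442
Hoxa1	Hoxa4, Hoxa9, Skap2	GGTTCA AGAAG AGTTCA	DR5	enhancer	1	1	1	1	1	1	chr6:52175533-52175549
Meis1	none	AGGCCA CTGAG AGGTCA	DR5	enhancer	1	1	1	1	1	0	chr11:18963875-18963891
Meis2	Dph6	AGGTCA AAAAC AGTTCA	DR5	enhancer	1	1	1	1	0	0	chr2:116071242-116071258
Nr2f1	none	GTGTCA A AGTTCA	DR1	enhancer	1	1	1	1	1	1	chr13:78200425-78200437
Nr2f2	none	GTGTCA A AGTTCA	DR1	enhancer	1	1	1	1	1	1	chr7:70361772-70361784
Pbx1	Lmx1a	GGGTCG CT GGGTCA	DR2	enhancer	1	1	1	1	0	0	chr1:169238844-169238857
Rarb	none	GGTTCA CCGAA AGTTCA	DR5	enhancer	1	1	1	1	0	0	chr14:16575513-16575529
Sox2	none	GGGTCA GG AGGTCA	DR2	enhancer	1	1	1	1	1	1	chr3:34679067-34679080
Tshz1	none	GGGTCA TTCAT AGTTCA	DR5	enhancer	1	1	1	1	0	0	chr18:84073476-84073492
Tshz1	none	AGGTCA GG AGGTGA	DR2	enhancer	1	1	1	1	0	0	chr18:83839858-83839871
Tshz1	none	GGGTGA ACTCA GGTTCA	DR5	enhancer	1	1	1	1	0	0	chr18:83839869-83839885
Zbtb16	none	GGGTCA CA GGGTCA	DR2	enhancer	1	1	1	1	0	1	chr9:48694721-48694734
Zbtb16	none	GGGTCA G GGGTTA	DR1	enhancer	1	1	1	1	0	0	chr9:48695827-48695839
Zfhx4	Pex2	GGGTCA GCCTG AGGTCA	DR5	enhancer	1	1	1	1	1	1	chr3:5388103-5388119
Zfp386	none	GAGTCA A AGGTCA	DR1	enhancer	1	0	1	1	0	0	chr12:117352086-117352098
Zfp638	none	GGTTCA GCCAA AGGTGA	DR5	enhancer	1	1	1	1	1	0	chr6:84976840-84976856
Fgf8	Poll, Btrc, Mrpl43, Chuk, Sema4g, Dnmbp, Erlin1, Entpd7, Got1, Slc25a28	GGGTCA GC AGTTCA	DR2	silencer	1	1	1	0	0	0	chr19:45747043-45747056
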