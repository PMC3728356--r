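# Chromosome 9q microsatellite marker map for the DFNA56 linkage scan.
# Genetic (cM) and physical (bp) positions as published for the 21 markers.
# n_alleles and allele_freqs are SYNTHETIC: the source states only that equal
# allele frequencies were used; "." in allele_freqs means equal (1/n_alleles).
name	chrom	cM	bp	n_alleles	allele_freqs
D9S1690	9	106.63	103143785	8	.
D9S1677	9	117.37	110981204	8	.
D9S1856	9	120.04	113986910	8	.
D9S289	9	120.77	115455388	8	.
D9S1824	9	122.23	115931926	8	.
D9S1776	9	123.33	116999255	8	.
D9S177	9	123.87	117499409	8	.
D9S154	9	125.63	118380667	8	.
D9S1872	9	129.74	120829322	8	.
D9S1116	9	130.52	122032251	8	.
D9S1682	9	132.09	124033006	8	.
D9S1881	9	135.85	126019300	8	.
D9S1840	9	136.47	126327340	8	.
D9S290	9	140.86	130567273	8	.
D9S1795	9	142.51	131346313	8	.
D9S1861	9	144.13	132310567	8	.
D9S1830	9	145.21	134655582	8	.
D9S164	9	147.91	135195754	8	.
D9S1826	9	159.61	137551425	8	.
D9S158	9	161.71	138202283	8	.
D9S1838	9	163.84	139519106	8	.
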