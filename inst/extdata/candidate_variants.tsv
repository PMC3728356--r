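# Eight candidate NS/SS/Indel variants shared by the three sequenced affected
# individuals after database and control subtraction. "-" in alt marks a
# deletion; "." marks a field that does not apply.
chromosome	position	ref	alt	gene	var_type	functional_class	codon_change	substitution
Chr6	151714872	A	T	AKAP12	snv	nonsynonymous	AAA-AtA	K1218I
Chr6	152671466	A	-	SYNE1	deletion	splice_site	.	.
Chr7	151601810	G	T	MLL3	snv	nonsynonymous	CCT-tCT	P309S
Chr9	116843116	C	A	TNC	snv	nonsynonymous	GTG-aTG	V1773M
Chr10	51282920	T	G	TIMM23	snv	nonsynonymous	AGA-gGA	R112G
Chr16	28511211	C	T	SULT1A2	snv	nonsynonymous	GAG-tAG	E217X
Chr17	77866494	A	C	CD7	snv	nonsynonymous	TAC-cAC	Y239H
Chr19	45786926	GAGGACAGTCCTGTCCAACAGGGAGG	-	SHKBP1	deletion	splice_site	.	.
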