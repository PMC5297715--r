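patient_id	gene	variant_class	consequence	transcript_change	codon_change	chromosome	position	ref_allele	alt_allele	zygosity	population_freq	category	impact
cohort	AHDC1	indel	frameshift			chr1	2010000	T	TG	het	NA	FS	High
cohort	LRRIQ3	indel	frameshift			chr1	2020000	G	GT	het	NA	FS	High
cohort	NOC3L	indel	frameshift			chr10	2030000	AT	A	het	NA	FS	High
cohort	TFAM	indel	frameshift			chr10	2040000	CA	C	het	NA	FS	High
cohort	TDG	indel	frameshift			chr12	2050000	G	GA	het	NA	FS	High
cohort	CCNK	indel	frameshift			chr14	2060000	G	GC	het	NA	FS	High
cohort	PAPOLA	indel	frameshift			chr14	2070000	TG	T	het	NA	FS	High
cohort	IRX5	indel	frameshift			chr16	2080000	AGG	A	het	NA	FS	High
cohort	ACSF2	indel	frameshift			chr17	2090000	T	TAA	het	NA	FS	High
cohort	KRT10	indel	frameshift			chr17	2100000	CCGCCG	C	het	NA	FS	High
cohort	KRT10	indel	frameshift			chr17	2110000	TG	T	het	NA	FS	High
cohort	CAPN12	indel	frameshift			chr19	2120000	G	GC	het	NA	FS	High
cohort	KCNC3	indel	frameshift			chr19	2130000	C	CG	het	NA	FS	High
cohort	SNED1	indel	frameshift			chr2	2140000	A	AC	het	NA	FS	High
cohort	C20orf132	indel	frameshift			chr20	2150000	GACCT	G	het	NA	FS	High
cohort	C20orf132	indel	frameshift			chr20	2160000	GC	G	het	NA	FS	High
cohort	C20orf132	indel	frameshift			chr20	2170000	GAGGAGTT	G	het	NA	FS	High
cohort	C20orf132	indel	frameshift			chr20	2180000	CG	C	het	NA	FS	High
cohort	C20orf132	indel	frameshift			chr20	2190000	TGG	T	het	NA	FS	High
cohort	TBP	indel	frameshift			chr6	2200000	AGC	A	het	NA	FS	High
cohort	TBP	indel	frameshift			chr6	2210000	AG	A	het	NA	FS	High
cohort	TFB1M	indel	frameshift			chr6	2220000	CAA	C	het	NA	FS	High
cohort	PHF2	indel	frameshift			chr9	2230000	A	AG	het	NA	FS	High
cohort	PLXNA3	indel	frameshift			chrX	2240000	T	TG	het	NA	FS	High
cohort	RBM10	indel	frameshift			chrX	2250000	CA	C	het	NA	FS	High
cohort	KRI1	indel	splice			chr19	2260000	CCATCA	C	het	NA	SSD	High
cohort	KRI1	indel	splice			chr19	2270000	CCATCA	C	het	NA	SSD	High
cohort	SCUBE2	indel	inframe			chr11	2280000	GGCA	G	het	NA	C & D	Moderate
cohort	ATXN2	indel	inframe			chr12	2290000	GGCT	G	het	NA	C & D	Moderate
cohort	MAP3K9	indel	inframe			chr14	2300000	GCCT	G	het	NA	C & D	Moderate
cohort	SAFB2	indel	inframe			chr19	2310000	GTAC	G	het	NA	C & D	Moderate
cohort	GIGYF2	indel	inframe			chr2	2320000	CACA	C	het	NA	C & D	Moderate
cohort	TPRN	indel	inframe			chr9	2330000	TTCC	T	het	NA	C & D	Moderate
cohort	AR	indel	inframe			chrX	2340000	AAGAGACTAGCCCCAG	A	het	NA	C & D	Moderate
cohort	KRTAP5-8	indel	inframe			chr11	2350000	T	TCCG	het	NA	C & I	Moderate
cohort	ATXN3	indel	inframe			chr14	2360000	C	CCTG	het	NA	C & I	Moderate
cohort	IRF2BPL	indel	inframe			chr14	2370000	C	CTGCTGT	het	NA	C & I	Moderate
cohort	HTT	indel	inframe			chr4	2380000	A	AACAGCC	het	NA	C & I	Moderate
cohort	ATAD2	indel	inframe			chr8	2390000	A	ATCG	het	NA	C & I	Moderate
cohort	APOBR	indel	inframe			chr16	2400000	TGGGACAGCCTCAGGAGGGGAGGAGGCC	T	het	NA	CD	Moderate
cohort	KDM6B	indel	inframe			chr17	2410000	TCAC	T	het	NA	CD	Moderate
cohort	MBD2	indel	inframe			chr18	2420000	CGCA	C	het	NA	CD	Moderate
cohort	ARID3A	indel	inframe			chr19	2430000	GGGA	G	het	NA	CD	Moderate
cohort	ADAM29	indel	inframe			chr4	2440000	GTGACACCCTCCCAGAGGCAACCTCAGT	G	het	NA	CD	Moderate
cohort	KCNQ5	indel	inframe			chr6	2450000	AGCG	A	het	NA	CD	Moderate
cohort	TBP	indel	inframe			chr6	2460000	GCAA	G	het	NA	CD	Moderate
cohort	RNF20	indel	inframe			chr9	2470000	TGTTGACTCTGAAGACTCA	T	het	NA	CD	Moderate
cohort	C10orf140	indel	inframe			chr10	2480000	C	CCCTCCT	het	NA	CI	Moderate
cohort	EP400	indel	inframe			chr12	2490000	A	ACAG	het	NA	CI	Moderate
cohort	EP400	indel	inframe			chr12	2500000	A	ACAG	het	NA	CI	Moderate
cohort	EP400	indel	inframe			chr12	2510000	G	GCAA	het	NA	CI	Moderate
cohort	KRTAP4-5	indel	inframe			chr17	2520000	T	TGGCAGCAGCTGGGGC	het	NA	CI	Moderate
cohort	ZNF814	indel	inframe			chr19	2530000	C	CATA	het	NA	CI	Moderate
cohort	HTT	indel	inframe			chr4	2540000	A	ACCGCCGCCG	het	NA	CI	Moderate
cohort	TBP	indel	inframe			chr6	2550000	A	ACAG	het	NA	CI	Moderate
cohort	TBP	indel	inframe			chr6	2560000	A	ACAG	het	NA	CI	Moderate
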