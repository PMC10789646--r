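Protein IDs	Protein names	Gene names	Peptide IDs	Potential contaminant	Reverse	Only identified by site	iBAQ p1	iBAQ p2	iBAQ m1	iBAQ m2
Q12906	Interleukin enhancer-binding factor 3	ILF3	1;2;3;4;5	 	 	 	8200000	7600000	950000	1020000
P68431	Histone H3.1	HIST1H3A	6;7;8	 	 	 	15000000	14200000	13800000	14500000
P62805	Histone H4	HIST1H4A	9;10;11;12	 	 	 	21000000	19800000	20400000	21500000
Q15366-2	Poly(rC)-binding protein 2	PCBP2	13;14;15;16	 	 	 	3100000	2800000	2900000	3050000
Q15366	Poly(rC)-binding protein 2 isoform	PCBP2	13;14;15;17	 	 	 	1200000	1350000	1280000	1190000
P02768	Serum albumin	ALB	18;19;20	+	 	 	5400000	5100000	5600000	5200000
REV__P04264	Reverse hit	KRT1	21;22	 	+	 	250000	180000	210000	190000
O60814	Histone H2B	HIST1H2BK	23;24;25	 	 	+	2600000	2450000	2380000	2550000
Q9NYF8	Bcl-2-associated transcription factor 1	BCLAF1	26;27;28;29	 	 	 	1900000	2100000		
P35659	Protein DEK	DEK	30;31	 	 	 	640000	720000	150000	
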