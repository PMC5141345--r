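patient	tumour	tumour_type	gsr	junction	vaf_pct
C-4	A	CRPC met	Deletion 1	chrX:66,804,042 (+)/chrX:66,816,507 (+)	7.32
C-4	A	CRPC met	Deletion 2	chrX:66,754,961 (+)/chrX:66,843,254 (+)	7.88
C-6	A	CRPC met	Deletion 1	chrX:66,934,778 (+)/chrX:66,942,396 (+)	46.99
C-6	A	CRPC met	Duplication	chrX:66,942,924 (+)/chrX:66,939,551 (+)	74.15
C-6	A	CRPC met	Deletion 2	chrX:66,940,040 (+)/chrX:66,943,474 (+)	42.68
C-6	B	CRPC met	Deletion 1	chrX:66,934,778 (+)/chrX:66,942,396 (+)	43.45
C-6	B	CRPC met	Duplication	chrX:66,942,924 (+)/chrX:66,939,551 (+)	49.19
C-6	B	CRPC met	Deletion 2	chrX:66,940,040 (+)/chrX:66,943,474 (+)	38.23
C-7	A	CRPC met	Deletion	chrX:49,150,734 (+)/chrX:66,779,010 (+)	4.26
C-7	B	CRPC met	Deletion	chrX:49,150,734 (+)/chrX:66,779,010 (+)	5.40
C-9	A	CRPC met	Translocation	chrX:66,909,163 (+)/TTTAG/chr11:79,397,735 (+)	13.74
C-12	A	CRPC met	Deletion	chrX:66,786,453 (+)/chrX:66,862,260 (+)	13.13
C-12	A	CRPC met	Duplication 1	chrX:66,765,788 (+)/chrX:66,738,768 (+)	4.71
C-12	A	CRPC met	Duplication 2	chrX:66,909,930 (+)/chrX:66,530,990 (+)	33.25
C-12	B	CRPC met	Deletion	chrX:66,786,453 (+)/chrX:66,862,260 (+)	46.28
C-12	B	CRPC met	Duplication 1	chrX:66,765,788 (+)/chrX:66,738,768 (+)	25.87
C-12	B	CRPC met	Duplication 3	chrX:66,767,448 (+)/chrX:66,026,083 (+)	5.66
C-14	A	CRPC met	Inversion 1	chrX:65,828,372 (-)/chrX:66,816,576 (+)	4.52
C-14	A	CRPC met	Inversion 2	chrX:66,919,966 (+)/chrX:67,012,163 (-)	1.62
C-14	B	CRPC met	Inversion 3	chrX:66,908,944 (-)/66,922,090 (+)	1.86
C-14	B	CRPC met	Duplication	chrX:66,929,712 (+)/chrX:66,921,594	2.65
P-1	TURP	local CRPC	Inversion	chrX:66,935,187 (+)/chrX:66,938,063 (-)	NA
P-14	TURP	local CRPC	Duplication	chrX:67,337,657 (+)/chrX:66,909,110 (+)	2.19
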