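chr1	0	2300000	p36.33	gneg
chr1	2300000	5400000	p36.32	gpos25
chr1	5400000	7200000	p36.31	gneg
chr1	7200000	9200000	p36.23	gpos25
chr1	9200000	12700000	p36.22	gneg
chr1	12700000	16200000	p36.21	gpos50
chr1	16200000	20400000	p36.13	gneg
chr1	20400000	23900000	p36.12	gpos25
chr1	23900000	28000000	p36.11	gneg
chr1	28000000	30200000	p35.3	gpos25
chr1	30200000	32400000	p35.2	gneg
chr1	32400000	34600000	p35.1	gpos25
chr1	34600000	46700000	p34	gneg
chr1	46700000	50700000	p33	gpos50
chr1	50700000	61300000	p32	gneg
chr1	61300000	84900000	p31	gpos50
chr1	84900000	94700000	p22	gneg
chr1	94700000	107200000	p21	gpos50
chr1	107200000	120600000	p13	gneg
chr1	120600000	121500000	p12	acen
chr1	121500000	125000000	q11	acen
chr1	125000000	142600000	q12	gvar
chr1	142600000	155100000	q21	gneg
chr1	155100000	165500000	q22	gpos25
chr1	165500000	173000000	q23	gneg
chr1	173000000	185800000	q24	gpos50
chr1	185800000	198700000	q25	gneg
chr1	198700000	211500000	q31	gpos50
chr1	211500000	224100000	q32	gneg
chr1	224100000	230500000	q41	gpos50
chr1	230500000	243700000	q42	gneg
chr1	243700000	246700000	q43	gpos25
chr1	246700000	249250621	q44	gneg
chr2	0	93300000	p11	gneg
chr2	93300000	243199373	q11	gneg
chr3	0	91000000	p11	gneg
chr3	91000000	198022430	q11	gneg
chr4	0	50400000	p11	gneg
chr4	50400000	191154276	q11	gneg
chr5	0	48400000	p11	gneg
chr5	48400000	180915260	q11	gneg
chr6	0	61000000	p11	gneg
chr6	61000000	171115067	q11	gneg
chr7	0	59900000	p11	gneg
chr7	59900000	159138663	q11	gneg
chr8	0	45600000	p11	gneg
chr8	45600000	146364022	q11	gneg
chr9	0	49000000	p11	gneg
chr9	49000000	141213431	q11	gneg
chr10	0	40200000	p11	gneg
chr10	40200000	135534747	q11	gneg
chr11	0	53700000	p11	gneg
chr11	53700000	135006516	q11	gneg
chr12	0	35800000	p11	gneg
chr12	35800000	133851895	q11	gneg
chr13	0	17900000	p11	gneg
chr13	17900000	115169878	q11	gneg
chr14	0	17600000	p11	gneg
chr14	17600000	107349540	q11	gneg
chr15	0	19000000	p11	gneg
chr15	19000000	102531392	q11	gneg
chr16	0	36600000	p11	gneg
chr16	36600000	90354753	q11	gneg
chr17	0	24000000	p11	gneg
chr17	24000000	81195210	q11	gneg
chr18	0	17200000	p11	gneg
chr18	17200000	78077248	q11	gneg
chr19	0	26500000	p11	gneg
chr19	26500000	59128983	q11	gneg
chr20	0	27500000	p11	gneg
chr20	27500000	63025520	q11	gneg
chr21	0	13200000	p11	gneg
chr21	13200000	48129895	q11	gneg
chr22	0	5000000	p13	gneg
chr22	5000000	10000000	p12	gpos25
chr22	10000000	14700000	p11	acen
chr22	14700000	17900000	q11.1	acen
chr22	17900000	25500000	q11.2	gneg
chr22	25500000	37600000	q12	gpos50
chr22	37600000	42600000	q13.1	gneg
chr22	42600000	44700000	q13.2	gpos25
chr22	44700000	46700000	q13.31	gneg
chr22	46700000	48100000	q13.32	gpos25
chr22	48100000	51304566	q13.33	gneg
chrX	0	24900000	p22	gneg
chrX	24900000	37600000	p21	gpos50
chrX	37600000	60600000	p11	gneg
chrX	60600000	65400000	q11	acen
chrX	65400000	76800000	q13	gneg
chrX	76800000	99100000	q21	gpos50
chrX	99100000	108300000	q22	gneg
chrX	108300000	117400000	q23	gpos25
chrX	117400000	122300000	q24	gneg
chrX	122300000	130400000	q25	gpos25
chrX	130400000	138900000	q26	gneg
chrX	138900000	148000000	q27	gpos25
chrX	148000000	155270560	q28	gneg
chrY	0	11600000	p11	gneg
chrY	11600000	28800000	q11	gneg
chrY	28800000	59373566	q12	gvar
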