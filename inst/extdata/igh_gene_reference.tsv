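gene	locus	functionality	locus_order	alias_of	exclude
IGHV6-1	IGHV	functional	1		FALSE
IGHV1-2	IGHV	functional	2		FALSE
IGHV1-3	IGHV	functional	3		FALSE
IGHV4-4	IGHV	functional	4		FALSE
IGHV7-4-1	IGHV	functional	5		FALSE
IGHV2-5	IGHV	functional	6		FALSE
IGHV3-7	IGHV	functional	7		FALSE
IGHV1-8	IGHV	functional	8		FALSE
IGHV3-9	IGHV	functional	9		FALSE
IGHV5-10-1	IGHV	functional	10		FALSE
IGHV3-11	IGHV	functional	11		FALSE
IGHV3-13	IGHV	functional	12		FALSE
IGHV3-15	IGHV	functional	13		FALSE
IGHV1-18	IGHV	functional	14		FALSE
IGHV3-20	IGHV	functional	15		FALSE
IGHV3-21	IGHV	functional	16		FALSE
IGHV3-23	IGHV	functional	17		FALSE
IGHV1-24	IGHV	functional	18		FALSE
IGHV2-26	IGHV	functional	19		FALSE
IGHV4-28	IGHV	functional	20		FALSE
IGHV4-30-1	IGHV	functional	21		TRUE
IGHV4-30-2	IGHV	functional	22		FALSE
IGHV3-30	IGHV	functional	23		FALSE
IGHV4-30-4	IGHV	functional	24		FALSE
IGHV3-30-3	IGHV	functional	25		FALSE
IGHV4-31	IGHV	functional	26		FALSE
IGHV3-33	IGHV	functional	27		FALSE
IGHV4-34	IGHV	functional	28		FALSE
IGHV4-38-2	IGHV	functional	29		FALSE
IGHV3-43	IGHV	functional	30		FALSE
IGHV1-45	IGHV	functional	31		FALSE
IGHV1-46	IGHV	functional	32		FALSE
IGHV3-48	IGHV	functional	33		FALSE
IGHV3-49	IGHV	functional	34		FALSE
IGHV5-51	IGHV	functional	35		FALSE
IGHV3-52	IGHV	pseudo	36		FALSE
IGHV3-53	IGHV	functional	37		FALSE
IGHV1-58	IGHV	functional	38		FALSE
IGHV4-59	IGHV	functional	39		FALSE
IGHV4-61	IGHV	functional	40		FALSE
IGHV3-64	IGHV	functional	41		FALSE
IGHV3-64D	IGHV	functional	42		FALSE
IGHV3-66	IGHV	functional	43		FALSE
IGHV1-69	IGHV	functional	44		FALSE
IGHV1-69D	IGHV	functional	45		TRUE
IGHV1-69-2	IGHV	functional	46		FALSE
IGHV2-70D	IGHV	functional	47		FALSE
IGHV2-70	IGHV	functional	48		FALSE
IGHV3-72	IGHV	functional	49		FALSE
IGHV3-73	IGHV	functional	50		FALSE
IGHV3-74	IGHV	functional	51		FALSE
IGHV7-81	IGHV	ORF	52		FALSE
IGHD1-1	IGHD	functional	1		FALSE
IGHD2-2	IGHD	functional	2		FALSE
IGHD3-3	IGHD	functional	3		FALSE
IGHD4-4	IGHD	functional	4	IGHD4-11	FALSE
IGHD5-5	IGHD	functional	5	IGHD5-18	FALSE
IGHD6-6	IGHD	functional	6		FALSE
IGHD1-7	IGHD	functional	7		FALSE
IGHD2-8	IGHD	functional	8		FALSE
IGHD3-9	IGHD	functional	9		FALSE
IGHD3-10	IGHD	functional	10		FALSE
IGHD4-11	IGHD	functional	11		FALSE
IGHD5-12	IGHD	functional	12		FALSE
IGHD6-13	IGHD	functional	13		FALSE
IGHD1-14	IGHD	functional	14		FALSE
IGHD2-15	IGHD	functional	15		FALSE
IGHD3-16	IGHD	functional	16		FALSE
IGHD4-17	IGHD	functional	17		FALSE
IGHD5-18	IGHD	functional	18		FALSE
IGHD6-19	IGHD	functional	19		FALSE
IGHD1-20	IGHD	functional	20		FALSE
IGHD2-21	IGHD	functional	21		FALSE
IGHD3-22	IGHD	functional	22		FALSE
IGHD4-23	IGHD	functional	23		FALSE
IGHD5-24	IGHD	functional	24		FALSE
IGHD6-25	IGHD	functional	25		FALSE
IGHD1-26	IGHD	functional	26		FALSE
IGHD7-27	IGHD	functional	27		FALSE
IGHJ1	IGHJ	functional	1		FALSE
IGHJ2	IGHJ	functional	2		FALSE
IGHJ3	IGHJ	functional	3		FALSE
IGHJ4	IGHJ	functional	4		FALSE
IGHJ5	IGHJ	functional	5		FALSE
IGHJ6	IGHJ	functional	6		FALSE
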