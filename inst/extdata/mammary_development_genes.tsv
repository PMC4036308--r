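symbol	chrom	start	stop	nb_snps
ADAM17	11	87798074	88040943	84
AREGB	6	91026256	91238391	53
BMP4	10	66651296	66855026	51
BMPR1A	28	41717915	41975988	55
CSN2	6	87079502	87288025	58
CCND1	29	47444380	47653820	43
DKK1	26	6752970	6955647	48
EDAR	11	44351547	44567795	31
EGF	6	16465618	16768065	103
EGFR	22	792005	1169280	81
ESR1	9	89869586	90355801	103
FGF1	7	55408007	55701836	65
FGF10	20	30510292	30719199	30
FGFR1	27	33150508	33400219	43
GH1	19	48668618	48872014	73
GHR	20	31790736	32299996	97
GLI2	2	72877209	73268370	82
GLI3	4	79344243	79858476	71
IGF1	5	66432877	66704734	49
IGF1R	21	8108822	8368093	61
IRS1	2	115690540	115894253	22
IRS2	12	88564525	88769181	64
LEF1	6	18235031	18550774	59
MFGE8	21	20789913	21004968	52
MMP14	10	21706054	21914533	43
MMP2	18	23728638	23955657	94
MMP3	15	5928011	6134595	52
MMP9	13	75366513	75573824	45
MSX1	6	105961463	106165759	56
MSX2	20	6260600	6465489	39
NRG1	27	27523938	27933470	79
NRG3	28	38201492	38451092	66
NTN1	19	28984419	29369338	87
PGR	15	8004485	8322755	64
PCBD1/TCF1	28	27126795	27331724	67
PRL	23	35005135	35213759	53
PRLR	20	38973246	39237480	56
PTHLH	5	82146522	82358858	30
PTH1R	22	53061302	53324114	48
PTH	15	39628332	39830868	31
TNFRSF11A	24	61139109	61375194	65
TNFSF11	12	12641069	12882474	73
RELN	4	44792394	45389293	131
SIRPA	13	53567570	53810792	80
SLIT2	6	41136589	41740789	145
SOCS1	25	9875299	10075970	56
SOCS2	5	23423981	23628860	46
SOCS3	19	54358856	54559555	62
STAT5A	19	42933597	43154075	59
STAT5B	19	42860226	43096671	60
TBX2	19	11843185	12051411	81
TBX3	17	62252245	62463636	45
TCF3	7	45499593	45730734	34
TCF4	24	54956409	55261459	73
TGFA	11	13772149	14086616	65
TGFB1	18	50671354	50885924	55
TGFBR1	8	64470093	64741796	64
TGFBR2	22	5041232	5333083	92
WAP	4	77111371	77312672	35
WNT10B	5	30913104	31114446	44
WNT11	15	56284700	56504335	51
WNT3	19	45921803	46171153	55
WNT5A	22	45996228	46212683	45
WNT6	2	107444683	107656681	64
N = 64				3968
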