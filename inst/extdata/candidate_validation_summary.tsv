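fusion_genes	sanger_sequencing	neighboring_genes	interchromosomal
ARL16-OXLD1	N	Y	N
RAD51AP1-DYRK4-1 *	Y	Y	N
D2HGDH	N	Y	N
SUMO3-UBE2G2 *	Y	Y	N
DMKN-KRTDAP *	Y	Y	N
DPM2-PIP5KL1	N	Y	N
MORF4L2-AS1-TMEM31 *	Y	Y	N
APEH-RNF123	N	Y	N
MFGE8-HAPLN3	N	Y	N
TBC1D23-NIT2 *	Y	Y	N
ZHX1-C8orf76 *	Y	Y	Y
TPD52L2-DNAJC5 *	Y	N	N
TBC1D24-ATP6VOC *	Y	Y	N
MSANTD3-TMEFF1 *	Y	Y	Y
SMOX-LINC012433 *	Y	Y	N
CLTC-VMP1 *	Y	N	N
RAPH1-OLA1-1 *	Y	N	N
RAPH1-OLA1-2 *	Y	N	N
RAD51AP1-DYRK4-2 *	Y	Y	Y
TLCD-RWDD3	N	Y	N
FARSA-SUCE2 *	Y	Y	N
VAMP1-CD27-AS1	N	Y	N
ZNF674-AS1-CHST7	N	Y	N
SUMF1-BHLHE40-AS1 *	Y	N	N
TPCN2-SMIM38	N	N	N
UBXN2A-MFSD2B	N	N	N
MLLT1-PFKP *	Y	N	Y
ASB16-AS1-PHF13	N	N	Y
POLDIP2-TNRC18	N	N	Y
CCDC32-CBX3	N	N	Y
BMERB1-CHP1	N	N	Y
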