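canonical	synonyms	biopsy_site	cell_type	organ	disease	age	sex	ethnicity
HeLa	Hela|HELA|CVCL_0030	uterine cervix	epithelial cell	uterine cervix	cervical adenocarcinoma	31	female	african american
MCF-7	MCF7|MCF 7	breast	epithelial cell	breast	breast adenocarcinoma	69	female	caucasian
A549	A-549	lung	epithelial cell	lung	lung adenocarcinoma	58	male	caucasian
HepG2	Hep G2|HEPG2	liver	hepatocyte	liver	hepatocellular carcinoma	15	male	caucasian
K562	K-562	bone marrow	lymphoblast	bone marrow	chronic myeloid leukemia	53	female	caucasian
Jurkat	JURKAT	blood	T cell	blood	acute T cell leukemia	14	male
A375	A-375	skin	melanocyte	skin	melanoma	54	female	caucasian
SK-MEL-28	SKMEL28|SK MEL 28	skin	melanocyte	skin	melanoma	51	male	caucasian
PC-3	PC3	bone	epithelial cell	prostate	prostate carcinoma	62	male	caucasian
LNCaP	LNCAP	lymph node	epithelial cell	prostate	prostate carcinoma	50	male	caucasian
HCT 116	HCT116|HCT-116	colon	epithelial cell	colon	colorectal carcinoma	48	male
SW480	SW-480	colon	epithelial cell	colon	colorectal adenocarcinoma	50	male	caucasian
MDA-MB-231	MDAMB231|MDA MB 231	breast	epithelial cell	breast	breast adenocarcinoma	51	female	caucasian
T-47D	T47D	breast	epithelial cell	breast	breast ductal carcinoma	54	female
U2OS	U-2 OS|U2-OS	bone	osteoblast	bone	osteosarcoma	15	female	caucasian
SH-SY5Y	SHSY5Y|SH SY5Y	bone marrow	neuroblast	brain	neuroblastoma	4	female
THP-1	THP1	blood	monocyte	blood	acute monocytic leukemia	1	male
Raji	RAJI	jaw	B cell	lymph node	Burkitt lymphoma	11	male	black
U-87 MG	U87|U87MG|U-87MG	brain	glial cell	brain	glioblastoma	44	male	caucasian
HT-29	HT29	colon	epithelial cell	colon	colorectal adenocarcinoma	44	female	caucasian
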