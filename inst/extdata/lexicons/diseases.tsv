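term_id	preferred_name	synonyms	cancer
DOID:399	tuberculosis	TB|phthisis	0
DOID:1909	melanoma	malignant melanoma	1
DOID:1612	breast cancer	breast carcinoma|mammary cancer	1
DOID:3458	breast adenocarcinoma		1
DOID:3007	breast ductal carcinoma	ductal carcinoma of the breast	1
DOID:1324	lung cancer	lung carcinoma	1
DOID:3910	lung adenocarcinoma	adenocarcinoma of lung	1
DOID:10283	prostate cancer	prostate carcinoma	1
DOID:9256	colorectal cancer	colorectal carcinoma|bowel cancer	1
DOID:0050861	colorectal adenocarcinoma		1
DOID:684	hepatocellular carcinoma	liver cell carcinoma|HCC	1
DOID:3702	cervical adenocarcinoma	adenocarcinoma of the cervix	1
DOID:3068	glioblastoma	glioblastoma multiforme|GBM	1
DOID:769	neuroblastoma		1
DOID:3347	osteosarcoma	osteogenic sarcoma	1
DOID:8552	chronic myeloid leukemia	CML|chronic myelogenous leukemia	1
DOID:9952	acute lymphoblastic leukemia	ALL	1
DOID:0060058	acute T cell leukemia	T-cell acute lymphoblastic leukemia	1
DOID:8864	acute monocytic leukemia	AMoL	1
DOID:8584	Burkitt lymphoma	Burkitt's lymphoma	1
DOID:2841	asthma	bronchial asthma	0
DOID:9352	type 2 diabetes mellitus	type 2 diabetes|T2DM	0
DOID:10652	Alzheimer disease	Alzheimer's disease|AD	0
DOID:14330	Parkinson disease	Parkinson's disease|PD	0
DOID:7148	rheumatoid arthritis	RA	0
DOID:8469	influenza	flu	0
DOID:0080600	COVID-19	SARS-CoV-2 infection	0
DOID:2043	hepatitis B	HBV infection	0
DOID:12365	malaria		0
DOID:552	pneumonia		0
DOID:8893	psoriasis		0
DOID:8778	Crohn disease	Crohn's disease	0
DOID:8577	ulcerative colitis	UC	0
DOID:9970	obesity		0
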