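term_id	preferred_name	synonyms
UBERON:0000167	oral cavity	mouth|buccal cavity
UBERON:0002048	lung	lungs|pulmonary tissue
UBERON:0002107	liver	hepatic tissue
UBERON:0000955	brain	encephalon
UBERON:0002097	skin	skin of body|cutaneous tissue
UBERON:0000310	breast	mammary gland
UBERON:0001155	colon	large bowel
UBERON:0002367	prostate	prostate gland
UBERON:0000002	uterine cervix	cervix|cervix uteri
UBERON:0000178	blood	peripheral blood|whole blood
UBERON:0002371	bone marrow	marrow
UBERON:0001474	bone	bone element
UBERON:0000029	lymph node	lymphatic node
UBERON:0002113	kidney	renal tissue
UBERON:0000948	heart	cardiac tissue
UBERON:0000945	stomach	gastric tissue
UBERON:0001264	pancreas	pancreatic tissue
UBERON:0002106	spleen	splenic tissue
UBERON:0001255	urinary bladder	bladder
UBERON:0001043	esophagus	oesophagus|gullet
UBERON:0002046	thyroid gland	thyroid
UBERON:0000992	ovary	ovarian tissue
UBERON:0000473	testis	testicle
UBERON:0001134	skeletal muscle	muscle|skeletal muscle tissue
UBERON:0001013	adipose tissue	fat|fat tissue
UBERON:0011595	jaw	jaw region
UBERON:0001723	tongue	lingual tissue
UBERON:0003126	trachea	windpipe
UBERON:0002108	small intestine	small bowel
UBERON:0000966	retina	retinal tissue
UBERON:0000970	eye	ocular tissue
UBERON:0001981	blood vessel	vasculature
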