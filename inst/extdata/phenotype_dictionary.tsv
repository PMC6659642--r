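term	canonical	source
platelet aggregation	platelet aggregation	EFO
protein c	protein c	EFO
bipolar disorder	bipolar disorder	SNOMED
type 2 diabetes	type 2 diabetes	EFO
type 1 diabetes	type 1 diabetes	EFO
blood pressure	blood pressure	EFO
systolic blood pressure	systolic blood pressure	EFO
diastolic blood pressure	diastolic blood pressure	EFO
body mass index	body mass index	MeSH
height	height	EFO
triglycerides	triglycerides	MeSH
cholesterol	cholesterol	MeSH
hdl cholesterol	hdl cholesterol	EFO
ldl cholesterol	ldl cholesterol	EFO
coronary artery disease	coronary artery disease	EFO
rheumatoid arthritis	rheumatoid arthritis	SNOMED
crohn's disease	crohn's disease	SNOMED
ulcerative colitis	ulcerative colitis	SNOMED
asthma	asthma	SNOMED
schizophrenia	schizophrenia	SNOMED
alzheimer disease	alzheimer disease	SNOMED
parkinson disease	parkinson disease	SNOMED
multiple sclerosis	multiple sclerosis	SNOMED
breast cancer	breast cancer	EFO
prostate cancer	prostate cancer	EFO
smoking behaviors	smoking behaviors	MeSH
alcohol consumption	alcohol consumption	MeSH
bone mineral density	bone mineral density	EFO
fasting glucose	fasting glucose	EFO
insulin resistance	insulin resistance	EFO
uric acid	uric acid	MeSH
serum creatinine	serum creatinine	MeSH
heart rate	heart rate	EFO
qt interval	qt interval	EFO
lung function	lung function	EFO
macular degeneration	macular degeneration	SNOMED
psoriasis	psoriasis	SNOMED
celiac disease	celiac disease	SNOMED
obesity	obesity	MeSH
waist circumference	waist circumference	EFO
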