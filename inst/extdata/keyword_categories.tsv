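# Keyword category dictionary: canonical lemma -> report column, per
# cancer type. Columns: cancer, keyword, category, label.
# A keyword may appear under more than one category for the same cancer
# (e.g. a drug discussed both for its side effects and as a treatment);
# such overlaps are preserved as-is.
stomach_cancer	ct	diagnosis	CT
stomach_cancer	mri	diagnosis	MRI
stomach_cancer	tumor_marker	diagnosis	tumor marker
stomach_cancer	lumbago	symptoms	lumbago
stomach_cancer	ts1	symptoms	TS-1
stomach_cancer	side_effects	symptoms	side effects
stomach_cancer	anticancer_drug	treatments	anti-cancer drug
stomach_cancer	ts1	treatments	TS-1
stomach_cancer	iron	treatments	administration of iron
colon_colorectal_cancer	ct	diagnosis	CT
colon_colorectal_cancer	pet	diagnosis	PET
colon_colorectal_cancer	elplat	symptoms	ELPLAT
colon_colorectal_cancer	side_effects	symptoms	side effects
colon_colorectal_cancer	chemotherapy	treatments	chemotherapy
colon_colorectal_cancer	diet	treatments	diet
colon_colorectal_cancer	nursing_care	others	nursing care
uterine_cervical_cancer	lymphedema	symptoms	lymphedema
uterine_cervical_cancer	education	others	educational activity
uterine_cervical_cancer	screening	others	screening
uterine_cervical_cancer	insurance	others	not covered by health insurance
uterine_cervical_cancer	vaccination	others	vaccination
uterine_cervical_cancer	official_support	others	official support
lung_cancer	ct	diagnosis	CT
lung_cancer	metastasis	symptoms	metastasis
lung_cancer	shoulder_pain	symptoms	shoulder pain
lung_cancer	back_pain	symptoms	back pain
lung_cancer	iressa	symptoms	Iressa
lung_cancer	side_effects	symptoms	side effects
lung_cancer	anticancer_drug	treatments	anti-cancer drug
lung_cancer	iressa	treatments	Iressa
lung_cancer	tarceva	treatments	Tarceva
lung_cancer	palliative_care	others	palliative care
breast_cancer	self_diagnosis	diagnosis	self-diagnosis
breast_cancer	metastasis	symptoms	metastasis
breast_cancer	lymphedema	symptoms	lymphedema
breast_cancer	chemotherapy	treatments	chemotherapy
breast_cancer	hormone_therapy	treatments	hormonal treatment
breast_cancer	palliative_care	others	palliative care
breast_cancer	pink_ribbon	others	the pink ribbon
leukemia	liver_test	diagnosis	liver function test
leukemia	liver_test	symptoms	liver function test
leukemia	foot_pain	symptoms	foot pain
leukemia	immunosuppression	symptoms	immunosuppression
leukemia	gvhd	symptoms	GVHD
leukemia	chemotherapy	treatments	chemotherapy
leukemia	steroid	treatments	steroid treatment
leukemia	transfusion	treatments	transfusion of red blood cells
leukemia	platelet	treatments	platelet transfusion
leukemia	aml	others	AML
leukemia	stem_cell_transplant	others	hematopoietic stem cell transplantation
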