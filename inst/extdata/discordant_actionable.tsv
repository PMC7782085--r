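gene	cnb_result	fna_result	patient_id	tumour_location	biopsy_site
CDKN2A	Homozygous deletion	Homozygous deletion	19	Anal canal	Liver
CDKN2A/B	Homozygous deletion	Normal	10	Stomach	Liver
CDKN2A/B	Homozygous deletion	Homozygous deletion	16	Breast	Lung
EGFR	NA	Amplification	43	Cervix	Peritoneum
FGFR1	Gain	Amplification	3	Breast	Lymph node
KRAS	Heterozygous mutation	WT	9	Pancreas	Liver
MAP2K4	Homozygous deletion	Heterozygous deletion	49	Breast	Liver
MAP2K4	Homozygous mutation	Heterozygous mutation	55	Breast	Liver
NF1	Heterozygous mutation	Homozygous mutation	19	Anal canal	Liver
PIK3CA	Absent	Heterozygous mutation	5	Pancreas	Liver
PIK3CA	Heterozygous mutation	Absent	50	Colon	Liver
PIK3R1	Homozygous deletion	Heterozygous deletion	2	Ovary	Liver
PIK3R1	Homozygous mutation	Heterozygous mutation	46	Breast	Liver
PTEN	Heterozygous mutation	Homozygous mutation	6	Breast	Subcutaneous
PTEN	Normal	Homozygous deletion	27	Muscle	Peritoneum
PTEN	Homozygous deletion	Normal	46	Breast	Liver
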