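symbol	inheritance	category	phenotype	sf_version	lof_gene
APC	AD	cancer	Familial adenomatous polyposis	v3.1	TRUE
BMPR1A	AD	cancer	Juvenile Polyposis Syndrome	v3.1	TRUE
BRCA1	AD	cancer	Hereditary breast and/or ovarian cancer	v3.1	TRUE
BRCA2	AD	cancer	Hereditary breast and/or ovarian cancer	v3.1	TRUE
MAX	AD	cancer	Hereditary paraganglioma-pheochromocytoma syndrome	v3.1	TRUE
MEN1	AD	cancer	Multiple endocrine neoplasia type 1	v3.1	TRUE
MLH1	AD	cancer	Lynch syndrome	v3.1	TRUE
MSH2	AD	cancer	Lynch syndrome	v3.1	TRUE
MSH6	AD	cancer	Lynch syndrome	v3.1	TRUE
MUTYH	AR	cancer	MUTYH-associated polyposis	v3.1	TRUE
NF2	AD	cancer	Neurofibromatosis type 2	v3.1	TRUE
PALB2	AD	cancer	Hereditary breast and/or ovarian cancer	v3.1	TRUE
PMS2	AD	cancer	Lynch syndrome	v3.1	TRUE
PTEN	AD	cancer	PTEN hamartoma tumor syndrome	v3.1	TRUE
RB1	AD	cancer	Retinoblastoma	v3.1	TRUE
RET	AD	cancer	Familial medullary thyroid cancer	v3.1	FALSE
SDHAF2	AD	cancer	Hereditary paraganglioma-pheochromocytoma syndrome	v3.1	TRUE
SDHB	AD	cancer	Hereditary paraganglioma-pheochromocytoma syndrome	v3.1	TRUE
SDHC	AD	cancer	Hereditary paraganglioma-pheochromocytoma syndrome	v3.1	TRUE
SDHD	AD	cancer	Hereditary paraganglioma-pheochromocytoma syndrome	v3.1	TRUE
SMAD4	AD	cancer	Juvenile Polyposis Syndrome	v3.1	TRUE
STK11	AD	cancer	Peutz-Jeghers syndrome	v3.1	TRUE
TMEM127	AD	cancer	Hereditary paraganglioma-pheochromocytoma syndrome	v3.1	TRUE
TP53	AD	cancer	Li-Fraumeni syndrome	v3.1	TRUE
TSC1	AD	cancer	Tuberous sclerosis complex	v3.1	TRUE
TSC2	AD	cancer	Tuberous sclerosis complex	v3.1	TRUE
VHL	AD	cancer	von Hippel-Lindau syndrome	v3.1	TRUE
WT1	AD	cancer	Wilms tumor	v3.1	TRUE
ACTA2	AD	cardiovascular	Familial thoracic aortic aneurysm and dissection	v3.1	FALSE
ACTC1	AD	cardiovascular	Hypertrophic cardiomyopathy	v3.1	FALSE
APOB	AD	cardiovascular	Familial hypercholesterolemia	v3.1	TRUE
BAG3	AD	cardiovascular	Dilated cardiomyopathy	v3.1	TRUE
CASQ2	AR	cardiovascular	Catecholaminergic polymorphic ventricular tachycardia	v3.1	TRUE
COL3A1	AD	cardiovascular	Ehlers-Danlos syndrome, vascular type	v3.1	TRUE
DES	AD	cardiovascular	Dilated cardiomyopathy	v3.1	FALSE
DSC2	AD	cardiovascular	Arrhythmogenic right ventricular cardiomyopathy	v3.1	TRUE
DSG2	AD	cardiovascular	Arrhythmogenic right ventricular cardiomyopathy	v3.1	TRUE
DSP	AD	cardiovascular	Arrhythmogenic right ventricular cardiomyopathy	v3.1	TRUE
FBN1	AD	cardiovascular	Marfan syndrome	v3.1	TRUE
FLNC	AD	cardiovascular	Dilated cardiomyopathy	v3.1	TRUE
KCNH2	AD	cardiovascular	Long QT syndrome 2	v3.1	TRUE
KCNQ1	AD	cardiovascular	Long QT syndrome 1	v3.1	TRUE
LDLR	SD	cardiovascular	Familial hypercholesterolemia	v3.1	TRUE
LMNA	AD	cardiovascular	Dilated cardiomyopathy	v3.1	TRUE
MYBPC3	AD	cardiovascular	Hypertrophic cardiomyopathy	v3.1	TRUE
MYH11	AD	cardiovascular	Familial thoracic aortic aneurysm and dissection	v3.1	FALSE
MYH7	AD	cardiovascular	Hypertrophic cardiomyopathy	v3.1	FALSE
MYL2	AD	cardiovascular	Hypertrophic cardiomyopathy	v3.1	FALSE
MYL3	AD	cardiovascular	Hypertrophic cardiomyopathy	v3.1	FALSE
PCSK9	AD	cardiovascular	Familial hypercholesterolemia	v3.1	FALSE
PKP2	AD	cardiovascular	Arrhythmogenic right ventricular cardiomyopathy	v3.1	TRUE
PRKAG2	AD	cardiovascular	Cardiomyopathy with glycogen storage	v3.1	FALSE
RBM20	AD	cardiovascular	Dilated cardiomyopathy	v3.1	FALSE
RYR2	AD	cardiovascular	Catecholaminergic polymorphic ventricular tachycardia	v3.1	FALSE
SCN5A	AD	cardiovascular	Long QT syndrome 3, Brugada syndrome	v3.1	TRUE
SMAD3	AD	cardiovascular	Loeys-Dietz syndrome	v3.1	TRUE
TGFBR1	AD	cardiovascular	Loeys-Dietz syndrome	v3.1	FALSE
TGFBR2	AD	cardiovascular	Loeys-Dietz syndrome	v3.1	FALSE
TMEM43	AD	cardiovascular	Arrhythmogenic right ventricular cardiomyopathy	v3.1	FALSE
TNNI3	AD	cardiovascular	Hypertrophic cardiomyopathy	v3.1	FALSE
TNNT2	AD	cardiovascular	Dilated cardiomyopathy	v3.1	FALSE
TPM1	AD	cardiovascular	Hypertrophic cardiomyopathy	v3.1	FALSE
TRDN	AR	cardiovascular	Catecholaminergic polymorphic ventricular tachycardia	v3.1	TRUE
TTN	AD	cardiovascular	Dilated cardiomyopathy	v3.1	TRUE
ACVRL1	AD	miscellaneous	Hereditary hemorrhagic telangiectasia	v3.1	TRUE
ATP7B	AR	miscellaneous	Wilson disease	v3.1	TRUE
BTD	AR	miscellaneous	Biotinidase deficiency	v3.1	TRUE
CACNA1S	AD	miscellaneous	Malignant hyperthermia	v3.1	FALSE
ENG	AD	miscellaneous	Hereditary hemorrhagic telangiectasia	v3.1	TRUE
GAA	AR	miscellaneous	Pompe disease	v3.1	TRUE
GLA	XL	miscellaneous	Fabry disease	v3.1	TRUE
HFE	AR	miscellaneous	Hereditary hemochromatosis	v3.1	TRUE
HMBS	AD	miscellaneous	Acute intermittent porphyria	v3.1	TRUE
HNF1A	AD	miscellaneous	Maturity-onset diabetes of the young	v3.1	TRUE
OTC	XL	miscellaneous	Ornithine transcarbamylase deficiency	v3.1	TRUE
RPE65	AR	miscellaneous	RPE65-related retinopathy	v3.1	TRUE
RYR1	AD	miscellaneous	Malignant hyperthermia	v3.1	FALSE
TTR	AD	miscellaneous	Hereditary TTR amyloidosis	v3.1	FALSE
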