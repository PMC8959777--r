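# Curated pathway annotations of force-related / force-sensitive lncRNAs,
# one row per (lncRNA, pathway, study); direction is the lncRNA's reported
# effect on osteogenic differentiation in that context.
lncrna_id	pathway	direction	context	reference_key
NEAT1	BMP	promotes	hBMSC; miR-29b-3p/BMP1 axis	B134
NEAT1	EZH2	unknown	cancer cell lines; mechanomemory to substrate stiffness via H3K27me3	B98
H19	FAK-ERK1/2-Runx2	promotes	hBMSC; tension; sponges miR-138 to release PTK2	B113
H19	ERK-MAPK	promotes	UMR-106; mechanical unloading; DNMT1/H19/Erk	B62
H19	Wnt/beta-catenin	promotes	UMR-106; mechanical unloading via Dkk4	B61
H19	IGF1	promotes	MC3T3-E1; matrix mineralization via miR-185-5p/IGF1	B116
H19	SATB2	promotes	hBMSC; miR-140-5p/SATB2	B5
H19	Wnt/beta-catenin	promotes	rEMSC; miR-22 and miR-141/beta-catenin	B31
H19	BMP	promotes	hASC; nanotopographical fiber alignment	B47
KCNQ1OT1	Cbfa1/Runx2	promotes	hBMSC; miR-320a/Smad5	B104
KCNQ1OT1	BMP2	promotes	hBMSC; miR-214/BMP2	B101
KCNQ1OT1	RUNX2/PPARgamma	promotes	mTSPC; via miR-138	B126
KCNQ1OT1	Wnt/beta-catenin	promotes	Hc-a cells; biomarker of delayed fracture healing	B32
TUG1	bFGF	promotes	mTSPC; ubiquitination of bFGF	B127
TUG1	Lin28A	promotes	hPDLSC	B36
TUG1	Smad	promotes	hPDLSC; miR-222-3p/Smad2/7	B112
TUG1	Wnt/beta-catenin	promotes	osteoblast proliferation and differentiation	B69
TUG1	Runx2	promotes	valve interstitial cells; miR-204/Runx2	B124
SNHG1	Wnt/beta-catenin	inhibits	hBMSC; miR-101/DKK1 axis	B117
SNHG1	p38 MAPK	inhibits	mBMSC; via Nedd4	B50
SNHG1	Wnt/beta-catenin	unknown	prostate cancer; binds EZH2	B11
SNHG1	PI3K/AKT/mTOR	unknown	prostate cancer; binds EZH2	B11
SNHG1	ROCK1	inhibits	osteosarcoma; miR-101-3p/ROCK1	B20
MALAT1	MAPK	inhibits	rBMSC	B139
MALAT1	YAP/TAZ	unknown	esophageal cancer; direct binding enhances YAP activity	B122
MALAT1	YAP/TAZ	unknown	acute pancreatitis; MALAT1/miR-194/YAP1 loop	B33
MALAT1	YAP/TAZ	unknown	non-small-cell lung cancer; MALAT1/miR-1914-3p/YAP loop	B51
MALAT1	Smad	promotes	valve interstitial cells; miR-204/Smad4	B118
MALAT1	RhoA/ROCK	unknown	osteosarcoma metastasis	B7
NORAD	YAP/TAZ	unknown	lung/breast cancer; repressed by YAP/TAZ-TEAD	B91
NORAD	TGF-beta	unknown	hepatocellular carcinoma; EMT-like phenotype	B55
NORAD	TGF-beta	unknown	hepatocellular carcinoma; via miR-202-5p	B121
NORAD	TGF-beta	unknown	breast cancer	B141
OIP5-AS1	TWIST11	promotes	valve interstitial cells; miR-137/TWIST11	B143
SNHG16	Wnt/beta-catenin	unknown	colorectal cancer; regulated by Wnt activity	B17
SNHG16	Wnt/beta-catenin	unknown	cervical cancer; SNHG16/miR-128 axis	B114
LINC00662	Wnt/beta-catenin	unknown	hepatocellular carcinoma; facilitates WNT3A secretion	B97
MCM3AP-AS1	HMGB1	unknown	chondrocytes; miR-142-3p/HMGB1	B30
FER1L4	AKT/FOXO3	promotes	PDLSC and mice; compression-induced autophagy	B43
DANCR	Notch	promotes	hPDLC and rats; miR-34a-5p/DANCR/Jagged1	B134
H19	Dkk4/Wnt	promotes	rats; hind limb unloading	B61
lncMUMA	miR-762/MyoD	promotes	C2C12 and mice; hind limb unloading	B137
PWRN1-209	integrin-FAK-ALP	promotes	hBMSC; titanium microtopography	B107
ODSM	miR-139-3p/ELK1	promotes	MC3T3-E1 and mice; hind limb unloading	B109
lncRNA-MSR	miRNA-152/TMSB4	unknown	human chondrocytes; cyclic tensile strain	B68
OGRU	miR-320-3p/Hoxa10-Runx2	promotes	MC3T3-E1 and mice; clinostat	B105
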