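# Curated force-sensitive miRNA table: one row per printed miRNA mention per study.
# evidence: functional (mechanistic experiments) or qPCR (expression profiling only).
# force_type: CTS cyclic tensile strain; CF compressive force; MG microgravity;
#   FSS fluid shear stress; OTM orthodontic tooth movement; ESW extracorporeal shockwave.
# osteo_sign: P promotes / N inhibits osteogenic differentiation.
# included: curation screen outcome (cross-species conservation of rodent miRNAs and
#   evidence reliability); only included rows enter the deduplicated reference list.
reference_key	evidence	cell_type	force_type	mirna	osteo_sign	included	target_pathways
B128	functional	prOB	CTS	miR-214	N	yes	Pten; beta-catenin; ATF4
B128	qPCR	prOB	CTS	miR-30d-5p	N	yes
B128	qPCR	prOB	CTS	miR-199a-3p	N	no
B128	qPCR	prOB	CTS	miR-31-5p	P	yes
B111	functional	hPDLSC	CTS	miR-21	P	yes	ACVR2B (TGF-beta)
B144	functional	FOB1.19	CTS	miR-103a	N	yes	Runx2
B34	qPCR	MC3T3-E1	CTS	miR-191*	P	no
B34	qPCR	MC3T3-E1	CTS	miR-3070a	P	no
B34	qPCR	MC3T3-E1	CTS	miR-218	N	no
B34	qPCR	MC3T3-E1	CTS	miR-33	N	yes
B130	functional	MLO-Y4	CTS	miR-29b	N	yes	inhibited IGF-1 secretion
B130	qPCR	MLO-Y4	CTS	miR-713	P	no
B130	qPCR	MLO-Y4	CTS	miR-706	P	no
B130	qPCR	MLO-Y4	CTS	miR-703	P	no
B130	qPCR	MLO-Y4	CTS	miR-574-3p	P	yes
B130	qPCR	MLO-Y4	CTS	miR-467b-3p	P	no
B130	qPCR	MLO-Y4	CTS	miR-466i/f-5p	P	no
B130	qPCR	MLO-Y4	CTS	miR-208a-3p	P	yes
B130	qPCR	MLO-Y4	CTS	miR-361-3p	N	no
B67	functional	rBMSC	CTS	miR-503-5p	N	yes
B67	qPCR	rBMSC	CTS	miR-34c-3p	P	yes
B67	qPCR	rBMSC	CTS	miR-326-5p	P	yes
B67	qPCR	rBMSC	CTS	miR-324-5p	N	no
B67	qPCR	rBMSC	CTS	miR-188-5p	N	no
B67	qPCR	rBMSC	CTS	miR-345-3p	N	no
B67	qPCR	rBMSC	CTS	miR-30a-5p	N	no
B67	qPCR	rBMSC	CTS	miR-29b-3p	N	yes
B67	qPCR	rBMSC	CTS	miR-351-3p	N	no
B115	qPCR	hPDLC	CTS	miR-138-5p	P	yes
B115	qPCR	hPDLC	CTS	miR-221-3p	P	yes
B115	qPCR	hPDLC	CTS	miR-132-3p	P	yes
B115	qPCR	hPDLC	CTS	miR-133a-3p	N	yes
B115	qPCR	hPDLC	CTS	miR-133a-5p	N	no
B115	qPCR	hPDLC	CTS	miR-210-3p	N	yes
B53	functional	hPDLC	CTS	miR-3198	N	yes	regulates OPG but not RANKL
B13	functional	hPDLC	CTS	miR-29 family (a,b,c)	P	yes	ECM genes Col1a1 Col3a1 Col5a1
B46	functional	MC3T3-E1	CF	miR-494-3p	N	yes	Fgfr2; Rock1
B46	qPCR	MC3T3-E1	CF	miR-146a-5p	N	no
B46	qPCR	MC3T3-E1	CF	miR-210-3p	N	yes
B46	qPCR	MC3T3-E1	CF	miR-1247-3p	N	no
B9	functional	hPDLC	CTS	miR-195-5p	N	yes	WNT3A; FGF2; BMPR1A
B10	qPCR	hPDLC	CTS	miR-195-5p	N	yes
B10	qPCR	hPDLC	CTS	miR-424-5p	N	yes
B10	qPCR	hPDLC	CTS	miR-1,297	N	yes
B10	qPCR	hPDLC	CTS	miR-3607-5p	N	yes
B10	qPCR	hPDLC	CTS	miR-145-5p	N	yes
B10	qPCR	hPDLC	CTS	miR-4,328	N	yes
B10	qPCR	hPDLC	CTS	miR-224-5p	N	yes
B70	functional	hADSC	CTS	let-7i-3p	N	yes	LEF1 (Wnt/beta-catenin)
B113	functional	hBMSC	CTS	miR-138	N	yes	PTK2 (FAK-ERK1/2-Runx2)
B64	functional	mADSC	CTS	miR-154-5p	N	yes	Wnt/PCP (RhoA/ROCK)
B76	functional	mOB	CTS	miR-20a	P	yes	IGF-I
B39	functional	hBMSC	ESW	miR-138	N	yes	FAK-ERK1/2-RUNX2
B131	functional	MC3T3-E1	MG	miR-30b/c/d/e	N	yes	Runx2
B84	functional	C2C12	MG	miR-494	N	yes	MYOD; BMPR-SMAD-RUNX2
B84	qPCR	C2C12	MG	miR-122a	P	yes
B84	qPCR	C2C12	MG	miR-340	P	yes
B103	functional	MC3T3-E1	MG	miR-33-5p	P	yes	Hmga2
B90	functional	MC3T3-E1	MG	miR-103	N	yes	Cav1.2 calcium channel
B41	functional	prOB	MG	miR-132-3p	N	yes	Ep300-Runx2
B41	qPCR	prOB	MG	miR-139-3p	N	no
B41	qPCR	prOB	MG	miR-339-3p	N	no
B41	qPCR	prOB	MG	miR-487b	P	yes
B41	qPCR	prOB	MG	miR-2,985	P	no
B41	qPCR	prOB	MG	miR-34b	P	yes
B82	functional	hPDLC	FSS	miR-132	P	yes	mTOR
B12	functional	hPDLC	OTM	miR-21	P	yes	Pdcd4 (C-fos)
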