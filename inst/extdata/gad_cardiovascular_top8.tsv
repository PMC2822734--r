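key	counterpart	count
Hypertension	ACE	47
Hypertension	AGT	24
Hypertension	NOS3	20
Hypertension	CYP11B2	18
Hypertension	GNB3	18
Hypertension	ADD1	16
Hypertension	AGTR1	12
Hypertension	ADRB2	8
Myocardial Infarction	NOS3	18
Myocardial Infarction	ACE	17
Myocardial Infarction	SERPINE1	11
Myocardial Infarction	ITGA2	7
Myocardial Infarction	LPL	6
Myocardial Infarction	APOE	6
Myocardial Infarction	GP1BA	5
Myocardial Infarction	F7	5
Coronary Disease	ACE	16
Coronary Disease	NOS3	12
Coronary Disease	PON1	11
Coronary Disease	APOB	11
Coronary Disease	APOE	8
Coronary Disease	LPL	7
Coronary Disease	AGT	6
Coronary Disease	SERPINE1	6
Coronary Artery Disease	NOS3	15
Coronary Artery Disease	PON1	9
Coronary Artery Disease	ACE	7
Coronary Artery Disease	APOA5	6
Coronary Artery Disease	APOE	5
Coronary Artery Disease	AGT	4
Coronary Artery Disease	ABCA1	4
Coronary Artery Disease	APOA1	4
Hypertrophy, Left Ventricular	ACE	15
Hypertrophy, Left Ventricular	GNB3	3
Hypertrophy, Left Ventricular	AGTR2	2
Hypertrophy, Left Ventricular	EDN1	2
Hypertrophy, Left Ventricular	TNNT2	2
Hypertrophy, Left Ventricular	NOS3	2
Hypertrophy, Left Ventricular	ENPP1	1
Hypertrophy, Left Ventricular	ACE2	1
Venous Thrombosis	F5	8
Venous Thrombosis	F2	5
Venous Thrombosis	SERPINE1	4
Venous Thrombosis	MTHFR	3
Venous Thrombosis	ABO	2
Venous Thrombosis	F8	2
Venous Thrombosis	JAK2	2
Venous Thrombosis	PROCR	2
Cardiovascular Diseases	APOE	7
Cardiovascular Diseases	CETP	6
Cardiovascular Diseases	ACE	5
Cardiovascular Diseases	NOS3	5
Cardiovascular Diseases	PON1	4
Cardiovascular Diseases	APOA5	4
Cardiovascular Diseases	APOC3	4
Cardiovascular Diseases	SERPINE1	3
Myocardial Ischemia	ACE	6
Myocardial Ischemia	LPL	5
Myocardial Ischemia	NOS3	2
Myocardial Ischemia	ITGB3	2
Myocardial Ischemia	APOB	2
Myocardial Ischemia	AGT	1
Myocardial Ischemia	AGTR1	1
Myocardial Ischemia	SELPLG	1
Arteriosclerosis	ACE	5
Arteriosclerosis	CD14	4
Arteriosclerosis	PON1	3
Arteriosclerosis	FGB	3
Arteriosclerosis	MTHFR	3
Arteriosclerosis	NOS3	3
Arteriosclerosis	APOE	3
Arteriosclerosis	TLR4	2
Cardiomyopathies	TTR	5
Cardiomyopathies	HFE	1
Cardiomyopathies	APOA1	1
Cardiomyopathies	HLADQB1	1
Cardiomyopathies	SOD2	1
Cardiomyopathies	CCR2	1
Cardiomyopathies	SELE	1
Cardiomyopathies	MMP9	1
Heart Failure	ADRA2C	5
Heart Failure	ADRB1	5
Heart Failure	ACE	3
Heart Failure	NOS3	3
Heart Failure	ADRB2	3
Heart Failure	AMPD1	2
Heart Failure	SCNN1B	1
Heart Failure	EDN1	1
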