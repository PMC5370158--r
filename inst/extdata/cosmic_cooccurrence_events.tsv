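cancer_type	gene	impact	reported	true	delta_score
HNSC	TP53	no_change	R119H	R119H	0.0
HNSC	SMARCA4	no_change	A503E	A503E	0.0
COAD	ALK	silent_to_missense	I1461I	I1461V	0.1
COAD	RET	no_change	A432V	A432V	0.0
COAD	PDE4DIP	missense_to_missense	C871Y	C871H	-3.0
SKCM	NACA	silent_to_missense	V226V	V336D	40.4
SKCM	ESR1	no_change	R243C	R243C	0.0
SKCM	PTPRB	missense_to_missense	R94S	R94N	1.4
SKCM	MLL3	missense_to_missense	T316I	T316F	15.0
SKCM	CNOT3	no_change	P243L	P243L	0.0
SKCM	FAT4	no_change	R4866K	R4866K	0.0
SKCM	MLL3	silent_to_missense	T316T	T316S	34.0
SKCM	FAT1	silent_to_missense	V482V	V482I	39.6
SKCM	BRCA2	no_change	L1521L	L1521L	0.0
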