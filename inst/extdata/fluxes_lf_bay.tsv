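# Published flux solutions: lung fibroblasts, DMSO vs molidustat (fmol/cell/h)
type	id	condition	flux	lb	ub
NET	GLUT	DMSO	6.12e+02	6.12e+02	6.12e+02
NET	GLUT	BAY	8.80e+02	8.80e+02	8.80e+02
NET	PYRR	DMSO	9.98e+01	9.95e+01	1.01e+02
NET	PYRR	BAY	6.06e+01	6.06e+01	6.06e+01
NET	MCT	DMSO	8.19e+02	8.17e+02	8.20e+02
NET	MCT	BAY	1.33e+03	1.33e+03	1.33e+03
NET	ALAR	DMSO	2.67e+00	2.36e+00	3.29e+00
NET	ALAR	BAY	5.98e+00	5.88e+00	6.24e+00
NET	GLNR	DMSO	3.78e+01	3.77e+01	3.79e+01
NET	GLNR	BAY	2.06e+01	2.06e+01	2.06e+01
NET	GLUR	DMSO	1.61e+01	1.56e+01	1.62e+01
NET	GLUR	BAY	1.68e+01	1.68e+01	1.68e+01
NET	ASPR	DMSO	2.36e+00	2.32e+00	2.49e+00
NET	ASPR	BAY	1.80e+00	1.80e+00	1.81e+00
NET	SERR	DMSO	1.03e+01	1.03e+01	1.06e+01
NET	SERR	BAY	2.50e+00	2.50e+00	2.50e+00
NET	CYSR	DMSO	2.79e+00	2.79e+00	2.95e+00
NET	CYSR	BAY	3.07e-01	3.06e-01	3.07e-01
NET	GLYR	DMSO	2.52e+00	2.30e+00	2.73e+00
NET	GLYR	BAY	5.52e-01	4.30e-01	7.45e-01
NET	HK	DMSO	6.12e+02	6.12e+02	6.12e+02
NET	HK	BAY	8.80e+02	8.80e+02	8.80e+02
NET	PGI	DMSO	6.09e+02	6.08e+02	6.09e+02
NET	PGI	BAY	8.42e+02	8.42e+02	8.42e+02
NET	PFK	DMSO	6.07e+02	6.07e+02	6.07e+02
NET	PFK	BAY	8.65e+02	8.65e+02	8.65e+02
NET	ALDO	DMSO	6.07e+02	6.07e+02	6.07e+02
NET	ALDO	BAY	8.65e+02	8.65e+02	8.65e+02
NET	TPI	DMSO	6.06e+02	6.06e+02	6.06e+02
NET	TPI	BAY	8.65e+02	8.65e+02	8.65e+02
NET	GAPDH	DMSO	1.21e+03	1.21e+03	1.21e+03
NET	GAPDH	BAY	1.74e+03	1.74e+03	1.74e+03
NET	ENO	DMSO	1.21e+03	1.21e+03	1.21e+03
NET	ENO	BAY	1.57e+03	1.57e+03	1.57e+03
NET	PK	DMSO	1.23e+03	1.19e+03	1.23e+03
NET	PK	BAY	1.65e+03	1.65e+03	1.65e+03
NET	LDH	DMSO	8.19e+02	8.17e+02	8.20e+02
NET	LDH	BAY	1.33e+03	1.33e+03	1.33e+03
NET	GPT1	DMSO	9.62e+00	9.44e+00	9.62e+00
NET	GPT1	BAY	9.36e+00	9.32e+00	9.42e+00
NET	GPT2	DMSO	1.14e-01	NA	NA
NET	GPT2	BAY	2.28e-07	-1.22e-05	6.41e-04
NET	G6PD	DMSO	2.02e-02	0.00e+00	1.08e+00
NET	G6PD	BAY	3.64e+01	3.64e+01	3.64e+01
NET	TK1	DMSO	-9.06e-01	-9.28e-01	-9.06e-01
NET	TK1	BAY	1.17e+01	1.17e+01	1.17e+01
NET	TA	DMSO	-9.06e-01	-9.28e-01	-9.06e-01
NET	TA	BAY	1.17e+01	1.17e+01	1.17e+01
NET	TK2	DMSO	-9.06e-01	-9.28e-01	-9.06e-01
NET	TK2	BAY	1.17e+01	1.17e+01	1.17e+01
NET	PYRT	DMSO	4.99e+02	4.97e+02	4.99e+02
NET	PYRT	BAY	5.50e+02	5.50e+02	5.50e+02
NET	PC	DMSO	2.11e+01	2.07e+01	2.17e+01
NET	PC	BAY	9.05e+01	9.05e+01	9.05e+01
NET	PEPCK	DMSO	1.36e+01	1.36e+01	1.37e+01
NET	PEPCK	BAY	8.58e+01	8.58e+01	8.58e+01
NET	ME2	DMSO	1.30e+01	1.28e+01	1.37e+01
NET	ME2	BAY	1.00e-07	0.00e+00	9.49e-06
NET	ME1	DMSO	3.20e-03	0.00e+00	1.73e+00
NET	ME1	BAY	1.00e-07	0.00e+00	2.15e-05
NET	FAO	DMSO	1.00e-07	0.00e+00	3.48e+00
NET	FAO	BAY	1.09e-04	8.34e-06	4.14e-02
NET	GLDH	DMSO	1.33e+01	1.31e+01	1.35e+01
NET	GLDH	BAY	-2.46e-01	-2.47e-01	-2.46e-01
NET	GLS	DMSO	3.40e+01	3.35e+01	3.42e+01
NET	GLS	BAY	1.88e+01	1.88e+01	1.88e+01
NET	PDH	DMSO	4.90e+02	4.90e+02	4.92e+02
NET	PDH	BAY	4.60e+02	4.60e+02	4.60e+02
NET	CS	DMSO	4.90e+02	4.84e+02	4.91e+02
NET	CS	BAY	4.60e+02	4.60e+02	4.60e+02
NET	IDH	DMSO	2.70e+01	2.70e+01	2.76e+01
NET	IDH	BAY	1.45e+01	1.45e+01	1.45e+01
NET	OGDH	DMSO	4.03e+01	3.99e+01	4.04e+01
NET	OGDH	BAY	1.43e+01	1.43e+01	1.43e+01
NET	SDH	DMSO	4.03e+01	3.99e+01	4.04e+01
NET	SDH	BAY	1.43e+01	1.43e+01	1.43e+01
NET	FH	DMSO	4.03e+01	3.99e+01	4.04e+01
NET	FH	BAY	1.43e+01	1.43e+01	1.43e+01
NET	MDH	DMSO	4.91e+02	4.91e+02	4.92e+02
NET	MDH	BAY	4.60e+02	4.60e+02	4.60e+02
NET	GOT	DMSO	7.91e+00	7.76e+00	7.98e+00
NET	GOT	BAY	4.46e+00	4.46e+00	4.46e+00
NET	PST	DMSO	4.03e-01	3.74e-01	5.04e-01
NET	PST	BAY	1.73e+02	1.73e+02	1.73e+02
NET	SHT	DMSO	6.63e+00	6.59e+00	6.65e+00
NET	SHT	BAY	2.85e+00	2.79e+00	2.93e+00
NET	CYST	DMSO	-3.88e+00	-3.91e+00	-3.87e+00
NET	CYST	BAY	2.03e-01	2.02e-01	2.03e-01
NET	SD	DMSO	2.80e+00	2.80e+00	2.80e+00
NET	SD	BAY	1.70e+02	1.70e+02	1.70e+02
NET	GLYS	DMSO	3.63e+00	3.50e+00	3.65e+00
NET	GLYS	BAY	1.41e+00	1.30e+00	1.46e+00
NET	BIOMASS	DMSO	2.39e-02	2.39e-02	2.50e-02
NET	BIOMASS	BAY	1.14e-02	1.14e-02	1.14e-02
NET	ACL	DMSO	4.63e+02	4.63e+02	4.66e+02
NET	ACL	BAY	4.45e+02	4.45e+02	4.45e+02
NET	LIPS	DMSO	4.34e+02	4.29e+02	4.34e+02
NET	LIPS	BAY	4.32e+02	4.32e+02	4.32e+02
NET	cPYR	DMSO	1.00e+00	9.99e-01	1.00e+00
NET	cPYR	BAY	1.00e-07	0.00e+00	1.00e+00
NET	mPYR	DMSO	1.00e-07	0.00e+00	9.83e-04
NET	mPYR	BAY	1.00e+00	0.00e+00	1.00e+00
NET	sPYR	DMSO	1.00e+00	1.00e+00	1.00e+00
NET	sPYR	BAY	1.00e+00	1.00e+00	1.00e+00
EXCH	MCT	DMSO	6.24e-04	0.00e+00	3.56e+00
EXCH	MCT	BAY	7.11e+02	7.11e+02	7.11e+02
EXCH	GLUR	DMSO	5.06e+00	4.82e+00	5.75e+00
EXCH	GLUR	BAY	3.48e+00	3.48e+00	3.48e+00
EXCH	PGI	DMSO	1.40e+06	1.39e+06	Inf
EXCH	PGI	BAY	4.31e+06	4.31e+06	4.31e+06
EXCH	ALDO	DMSO	2.38e+02	2.38e+02	2.38e+02
EXCH	ALDO	BAY	1.02e+03	1.02e+03	1.02e+03
EXCH	TPI	DMSO	9.99e+06	NA	Inf
EXCH	TPI	BAY	7.57e+03	7.57e+03	7.57e+03
EXCH	GAPDH	DMSO	5.81e+02	5.81e+02	7.25e+02
EXCH	GAPDH	BAY	1.09e+02	1.07e+02	1.09e+02
EXCH	LDH	DMSO	2.65e+03	2.58e+03	2.65e+03
EXCH	LDH	BAY	4.92e+01	4.91e+01	4.94e+01
EXCH	GPT1	DMSO	1.00e-07	0.00e+00	5.60e-02
EXCH	GPT1	BAY	2.45e+03	2.45e+03	2.45e+03
EXCH	GPT2	DMSO	1.00e-07	0.00e+00	5.65e-02
EXCH	GPT2	BAY	1.00e-07	0.00e+00	1.20e-05
EXCH	TK1	DMSO	1.28e+06	9.01e+03	Inf
EXCH	TK1	BAY	1.00e+07	-Inf	Inf
EXCH	TA	DMSO	8.89e+00	8.88e+00	9.53e+00
EXCH	TA	BAY	5.10e+01	5.10e+01	5.10e+01
EXCH	TK2	DMSO	6.93e+00	5.12e+00	6.98e+00
EXCH	TK2	BAY	1.00e-07	0.00e+00	1.56e-04
EXCH	GLDH	DMSO	5.63e+03	4.43e+03	5.66e+03
EXCH	GLDH	BAY	1.42e+03	1.42e+03	1.42e+03
EXCH	GLS	DMSO	1.27e+00	1.20e+00	1.50e+00
EXCH	GLS	BAY	5.52e-01	5.51e-01	5.55e-01
EXCH	IDH	DMSO	3.36e+00	3.24e+00	3.92e+00
EXCH	IDH	BAY	4.66e+00	4.66e+00	4.66e+00
EXCH	SDH	DMSO	4.30e+02	4.30e+02	1.46e+06
EXCH	SDH	BAY	1.04e+04	1.04e+04	1.04e+04
EXCH	FH	DMSO	7.29e+06	-Inf	Inf
EXCH	FH	BAY	4.56e+06	4.56e+06	4.56e+06
EXCH	MDH	DMSO	5.49e+02	5.47e+02	5.49e+02
EXCH	MDH	BAY	1.00e-07	0.00e+00	6.30e-03
EXCH	GOT	DMSO	1.04e+02	1.04e+02	1.04e+02
EXCH	GOT	BAY	4.76e+05	4.76e+05	4.76e+05
EXCH	SHT	DMSO	1.39e+00	1.37e+00	1.41e+00
EXCH	SHT	BAY	1.86e+03	1.86e+03	1.86e+03
EXCH	CYST	DMSO	1.25e-07	0.00e+00	4.22e-02
EXCH	CYST	BAY	1.33e-01	1.33e-01	1.33e-01
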