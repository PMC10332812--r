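# Published flux solutions: PASMCs, 21% vs 0.5% oxygen (fmol/cell/h)
type	id	condition	flux	lb	ub
NET	GLUT	21pct	4.28e+02	4.28e+02	4.28e+02
NET	GLUT	0.5pct	3.65e+02	3.65e+02	3.65e+02
NET	PYRR	21pct	1.04e+02	1.02e+02	1.09e+02
NET	PYRR	0.5pct	4.53e+01	4.31e+01	4.57e+01
NET	MCT	21pct	8.01e+02	8.01e+02	8.04e+02
NET	MCT	0.5pct	6.49e+02	6.49e+02	6.49e+02
NET	ALAR	21pct	1.43e+01	1.43e+01	1.46e+01
NET	ALAR	0.5pct	7.83e+00	7.83e+00	8.24e+00
NET	GLNR	21pct	7.73e+01	7.53e+01	7.73e+01
NET	GLNR	0.5pct	1.77e+02	1.77e+02	1.77e+02
NET	GLUR	21pct	2.53e+01	2.52e+01	2.54e+01
NET	GLUR	0.5pct	1.19e+01	1.19e+01	1.22e+01
NET	ASPR	21pct	7.01e+00	6.99e+00	7.02e+00
NET	ASPR	0.5pct	6.92e+00	6.84e+00	7.00e+00
NET	SERR	21pct	2.54e+00	2.48e+00	2.55e+00
NET	SERR	0.5pct	2.57e+00	2.55e+00	2.57e+00
NET	CYSR	21pct	6.39e+00	6.34e+00	6.45e+00
NET	CYSR	0.5pct	3.75e+00	3.75e+00	3.75e+00
NET	GLYR	21pct	3.66e-01	3.03e-01	4.19e-01
NET	GLYR	0.5pct	4.06e-01	3.86e-01	4.25e-01
NET	HK	21pct	4.28e+02	4.28e+02	4.28e+02
NET	HK	0.5pct	3.65e+02	3.65e+02	3.65e+02
NET	PGI	21pct	4.06e+02	4.06e+02	4.07e+02
NET	PGI	0.5pct	3.62e+02	3.62e+02	3.63e+02
NET	PFK	21pct	4.17e+02	4.17e+02	4.18e+02
NET	PFK	0.5pct	3.61e+02	3.60e+02	3.61e+02
NET	ALDO	21pct	4.17e+02	4.17e+02	4.18e+02
NET	ALDO	0.5pct	3.61e+02	3.60e+02	3.61e+02
NET	TPI	21pct	4.16e+02	4.16e+02	4.16e+02
NET	TPI	0.5pct	3.60e+02	3.60e+02	3.60e+02
NET	GAPDH	21pct	8.39e+02	8.39e+02	8.41e+02
NET	GAPDH	0.5pct	7.21e+02	7.21e+02	7.21e+02
NET	ENO	21pct	8.36e+02	8.35e+02	8.53e+02
NET	ENO	0.5pct	7.20e+02	7.20e+02	7.20e+02
NET	PK	21pct	9.31e+02	9.30e+02	9.31e+02
NET	PK	0.5pct	9.24e+02	9.24e+02	9.24e+02
NET	LDH	21pct	8.01e+02	8.01e+02	8.04e+02
NET	LDH	0.5pct	6.49e+02	6.49e+02	6.49e+02
NET	GPT1	21pct	1.64e+02	1.62e+02	1.92e+02
NET	GPT1	0.5pct	-1.36e+01	-1.39e+01	-1.35e+01
NET	GPT2	21pct	-1.43e+02	-1.43e+02	-1.42e+02
NET	GPT2	0.5pct	2.62e+01	2.51e+01	2.65e+01
NET	G6PD	21pct	1.89e+01	1.57e+01	1.93e+01
NET	G6PD	0.5pct	1.16e-07	0.00e+00	1.10e-03
NET	TK1	21pct	5.46e+00	4.44e+00	5.96e+00
NET	TK1	0.5pct	-6.15e-01	-6.15e-01	-5.77e-01
NET	TA	21pct	5.46e+00	4.44e+00	5.96e+00
NET	TA	0.5pct	-6.15e-01	-6.15e-01	-5.77e-01
NET	TK2	21pct	5.46e+00	4.44e+00	5.96e+00
NET	TK2	0.5pct	-6.15e-01	-6.15e-01	-5.77e-01
NET	PYRT	21pct	7.60e+01	7.59e+01	7.66e+01
NET	PYRT	0.5pct	3.36e+02	3.36e+02	3.36e+02
NET	PC	21pct	6.30e+01	6.29e+01	6.59e+01
NET	PC	0.5pct	2.37e+02	2.36e+02	2.37e+02
NET	PEPCK	21pct	9.51e+01	9.51e+01	9.53e+01
NET	PEPCK	0.5pct	2.03e+02	2.03e+02	2.04e+02
NET	ME2	21pct	1.20e-03	0.00e+00	5.20e-03
NET	ME2	0.5pct	1.82e+02	1.81e+02	1.82e+02
NET	ME1	21pct	3.29e-05	0.00e+00	1.15e+00
NET	ME1	0.5pct	5.91e-05	0.00e+00	8.06e-02
NET	FAO	21pct	1.00e-07	0.00e+00	1.32e-02
NET	FAO	0.5pct	1.15e-04	0.00e+00	1.56e-01
NET	GLDH	21pct	4.43e+01	4.42e+01	4.45e+01
NET	GLDH	0.5pct	1.59e+02	1.59e+02	1.59e+02
NET	GLS	21pct	7.38e+01	7.36e+01	7.38e+01
NET	GLS	0.5pct	1.74e+02	1.74e+02	1.74e+02
NET	PDH	21pct	1.56e+02	1.48e+02	1.66e+02
NET	PDH	0.5pct	2.55e+02	2.55e+02	2.55e+02
NET	CS	21pct	1.56e+02	1.56e+02	1.58e+02
NET	CS	0.5pct	2.55e+02	2.55e+02	2.55e+02
NET	IDH	21pct	2.11e+01	2.10e+01	2.11e+01
NET	IDH	0.5pct	2.16e+01	2.16e+01	2.16e+01
NET	OGDH	21pct	6.54e+01	6.51e+01	6.59e+01
NET	OGDH	0.5pct	1.81e+02	1.80e+02	1.81e+02
NET	SDH	21pct	6.54e+01	6.51e+01	6.59e+01
NET	SDH	0.5pct	1.81e+02	1.80e+02	1.81e+02
NET	FH	21pct	6.54e+01	6.51e+01	6.59e+01
NET	FH	0.5pct	1.81e+02	1.80e+02	1.81e+02
NET	MDH	21pct	2.01e+02	2.01e+02	2.01e+02
NET	MDH	0.5pct	2.32e+02	2.32e+02	2.33e+02
NET	GOT	21pct	1.22e+01	1.17e+01	1.24e+01
NET	GOT	0.5pct	1.07e+01	1.06e+01	1.07e+01
NET	PST	21pct	2.69e+00	2.57e+00	2.80e+00
NET	PST	0.5pct	7.12e-01	7.01e-01	7.21e-01
NET	SHT	21pct	5.19e+00	5.15e+00	5.20e+00
NET	SHT	0.5pct	3.82e+00	3.81e+00	3.86e+00
NET	CYST	21pct	-1.12e+01	-1.17e+01	-1.11e+01
NET	CYST	0.5pct	-6.35e+00	-6.35e+00	-6.35e+00
NET	SD	21pct	6.39e+00	6.23e+00	6.44e+00
NET	SD	0.5pct	2.33e+00	2.33e+00	2.33e+00
NET	GLYS	21pct	2.39e+00	2.36e+00	2.42e+00
NET	GLYS	0.5pct	1.80e+00	1.79e+00	1.81e+00
NET	BIOMASS	21pct	2.77e-02	2.70e-02	2.79e-02
NET	BIOMASS	0.5pct	2.00e-02	2.00e-02	2.00e-02
NET	ACL	21pct	1.35e+02	1.34e+02	1.38e+02
NET	ACL	0.5pct	2.33e+02	2.33e+02	2.33e+02
NET	LIPS	21pct	1.08e+02	9.99e+01	1.08e+02
NET	LIPS	0.5pct	2.14e+02	2.14e+02	2.14e+02
NET	cPYR	21pct	5.77e-01	5.64e-01	5.92e-01
NET	cPYR	0.5pct	1.00e+00	9.96e-01	1.00e+00
NET	mPYR	21pct	4.23e-01	4.08e-01	4.36e-01
NET	mPYR	0.5pct	1.00e-07	0.00e+00	4.40e-03
NET	sPYR	21pct	1.00e+00	1.00e+00	1.00e+00
NET	sPYR	0.5pct	1.00e+00	1.00e+00	1.00e+00
EXCH	MCT	21pct	1.00e-07	0.00e+00	1.36e+02
EXCH	MCT	0.5pct	1.64e+03	1.63e+03	1.65e+03
EXCH	GLUR	21pct	1.00e-07	0.00e+00	2.27e-02
EXCH	GLUR	0.5pct	5.69e-05	0.00e+00	1.71e-02
EXCH	PGI	21pct	4.88e+06	4.88e+06	Inf
EXCH	PGI	0.5pct	9.92e+06	9.85e+04	Inf
EXCH	ALDO	21pct	2.89e+02	2.80e+02	2.89e+02
EXCH	ALDO	0.5pct	2.57e+02	2.56e+02	2.57e+02
EXCH	TPI	21pct	9.86e+06	-Inf	Inf
EXCH	TPI	0.5pct	1.65e+03	1.63e+03	1.68e+03
EXCH	GAPDH	21pct	1.12e+03	0.00e+00	5.88e+05
EXCH	GAPDH	0.5pct	1.00e-07	0.00e+00	2.27e-01
EXCH	LDH	21pct	1.47e+03	1.39e+03	1.47e+03
EXCH	LDH	0.5pct	4.49e+02	4.49e+02	4.49e+02
EXCH	GPT1	21pct	2.74e+02	2.73e+02	2.77e+02
EXCH	GPT1	0.5pct	1.00e-07	0.00e+00	4.28e-02
EXCH	GPT2	21pct	1.38e+02	1.38e+02	1.49e+02
EXCH	GPT2	0.5pct	9.64e+01	0.00e+00	1.01e+02
EXCH	TK1	21pct	7.99e+02	7.97e+02	8.08e+02
EXCH	TK1	0.5pct	3.54e+01	3.54e+01	3.55e+01
EXCH	TA	21pct	1.53e-01	0.00e+00	5.82e-01
EXCH	TA	0.5pct	2.55e+00	2.54e+00	2.57e+00
EXCH	TK2	21pct	3.33e+00	2.62e+00	3.35e+00
EXCH	TK2	0.5pct	1.29e+01	1.29e+01	1.29e+01
EXCH	GLDH	21pct	5.36e+02	5.34e+02	8.37e+02
EXCH	GLDH	0.5pct	1.23e+03	1.23e+03	1.23e+03
EXCH	GLS	21pct	3.20e-01	0.00e+00	2.74e+00
EXCH	GLS	0.5pct	1.12e+00	1.07e+00	1.74e+00
EXCH	IDH	21pct	1.04e+01	1.02e+01	1.04e+01
EXCH	IDH	0.5pct	6.30e+01	6.30e+01	6.31e+01
EXCH	SDH	21pct	2.78e-01	0.00e+00	Inf
EXCH	SDH	0.5pct	3.34e+06	3.34e+06	3.34e+06
EXCH	FH	21pct	1.03e-04	0.00e+00	1.58e+01
EXCH	FH	0.5pct	2.18e+02	2.18e+02	2.18e+02
EXCH	MDH	21pct	1.01e+03	8.27e+02	1.01e+03
EXCH	MDH	0.5pct	3.67e+03	3.67e+03	3.69e+03
EXCH	GOT	21pct	2.27e+02	2.27e+02	2.47e+02
EXCH	GOT	0.5pct	1.54e+01	1.54e+01	1.55e+01
EXCH	SHT	21pct	3.55e+00	3.52e+00	3.59e+00
EXCH	SHT	0.5pct	1.60e-01	1.36e-01	1.70e-01
EXCH	CYST	21pct	1.04e+03	1.03e+03	1.04e+03
EXCH	CYST	0.5pct	2.00e-03	0.00e+00	2.00e-03
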