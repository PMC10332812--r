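# Published flux solutions: lung fibroblasts, 21% vs 0.5% oxygen (fmol/cell/h)
type	id	condition	flux	lb	ub
NET	GLUT	21pct	5.14e+02	5.11e+02	5.21e+02
NET	GLUT	0.5pct	4.41e+02	4.26e+02	4.58e+02
NET	PYRR	21pct	7.56e+01	7.31e+01	7.96e+01
NET	PYRR	0.5pct	6.21e+01	5.83e+01	6.60e+01
NET	MCT	21pct	9.99e+02	9.98e+02	1.02e+03
NET	MCT	0.5pct	8.91e+02	8.62e+02	9.25e+02
NET	ALAR	21pct	2.25e+00	1.95e+00	2.49e+00
NET	ALAR	0.5pct	5.84e-01	1.10e-03	1.16e+00
NET	GLNR	21pct	4.15e+01	4.06e+01	4.16e+01
NET	GLNR	0.5pct	1.43e+01	1.26e+01	1.94e+01
NET	GLUR	21pct	1.62e+01	1.58e+01	1.68e+01
NET	GLUR	0.5pct	7.55e+00	6.88e+00	8.15e+00
NET	ASPR	21pct	2.57e+00	2.53e+00	2.68e+00
NET	ASPR	0.5pct	1.08e+00	4.17e-01	1.69e+00
NET	SERR	21pct	1.42e+01	1.35e+01	1.49e+01
NET	SERR	0.5pct	5.49e+00	4.99e+00	6.06e+00
NET	CYSR	21pct	4.41e+00	4.23e+00	4.58e+00
NET	CYSR	0.5pct	1.65e+00	1.32e+00	2.08e+00
NET	GLYR	21pct	2.05e+00	1.90e+00	2.15e+00
NET	GLYR	0.5pct	2.60e-01	2.00e-02	4.92e-01
NET	HK	21pct	5.14e+02	5.11e+02	5.21e+02
NET	HK	0.5pct	4.41e+02	4.26e+02	4.58e+02
NET	PGI	21pct	5.11e+02	4.99e+02	5.24e+02
NET	PGI	0.5pct	4.23e+02	4.04e+02	4.40e+02
NET	PFK	21pct	5.09e+02	5.00e+02	5.12e+02
NET	PFK	0.5pct	4.32e+02	4.17e+02	4.49e+02
NET	ALDO	21pct	5.09e+02	5.00e+02	5.12e+02
NET	ALDO	0.5pct	4.32e+02	4.17e+02	4.49e+02
NET	TPI	21pct	5.08e+02	5.06e+02	5.08e+02
NET	TPI	0.5pct	4.31e+02	4.15e+02	4.48e+02
NET	GAPDH	21pct	1.02e+03	9.96e+02	1.04e+03
NET	GAPDH	0.5pct	8.69e+02	8.35e+02	9.03e+02
NET	ENO	21pct	1.01e+03	9.99e+02	1.03e+03
NET	ENO	0.5pct	8.68e+02	8.36e+02	9.00e+02
NET	PK	21pct	1.04e+03	9.95e+02	1.04e+03
NET	PK	0.5pct	8.78e+02	8.36e+02	9.21e+02
NET	LDH	21pct	9.99e+02	9.98e+02	1.02e+03
NET	LDH	0.5pct	8.91e+02	8.62e+02	9.25e+02
NET	GPT1	21pct	1.19e+01	9.12e+00	1.19e+01
NET	GPT1	0.5pct	5.55e+00	-9.08e+02	6.13e+00
NET	GPT2	21pct	-2.58e+00	-4.56e+00	2.87e+00
NET	GPT2	0.5pct	-2.40e-03	-3.22e+01	9.11e+02
NET	G6PD	21pct	1.26e-07	0.00e+00	3.91e-01
NET	G6PD	0.5pct	1.62e+01	4.41e+00	2.89e+01
NET	TK1	21pct	-9.11e-01	-9.29e-01	-8.30e-01
NET	TK1	0.5pct	4.76e+00	-1.22e-01	9.62e+00
NET	TA	21pct	-9.11e-01	-9.29e-01	-8.30e-01
NET	TA	0.5pct	4.76e+00	-1.22e-01	9.62e+00
NET	TK2	21pct	-9.11e-01	-9.29e-01	-8.30e-01
NET	TK2	0.5pct	4.76e+00	-1.22e-01	9.62e+00
NET	PYRT	21pct	1.16e+02	1.16e+02	1.19e+02
NET	PYRT	0.5pct	4.42e+01	3.82e+01	9.58e+02
NET	PC	21pct	1.88e+01	1.74e+01	1.91e+01
NET	PC	0.5pct	1.37e+01	9.82e+00	2.69e+01
NET	PEPCK	21pct	2.56e+01	1.58e+01	2.57e+01
NET	PEPCK	0.5pct	9.66e+00	0.00e+00	2.60e+01
NET	ME2	21pct	2.05e+00	9.51e-02	2.68e+00
NET	ME2	0.5pct	1.00e-07	0.00e+00	2.25e+01
NET	ME1	21pct	2.78e-02	0.00e+00	2.63e+01
NET	ME1	0.5pct	8.71e-05	0.00e+00	2.52e+01
NET	FAO	21pct	1.00e-07	0.00e+00	2.13e+00
NET	FAO	0.5pct	6.58e-06	0.00e+00	7.73e-01
NET	GLDH	21pct	1.71e+01	1.56e+01	1.84e+01
NET	GLDH	0.5pct	9.11e-01	-6.16e-01	7.27e+00
NET	GLS	21pct	3.78e+01	3.60e+01	3.86e+01
NET	GLS	0.5pct	1.17e+01	1.01e+01	1.70e+01
NET	PDH	21pct	1.02e+02	8.76e+01	1.15e+02
NET	PDH	0.5pct	3.05e+01	2.86e+01	5.24e+01
NET	CS	21pct	1.02e+02	8.30e+01	1.11e+02
NET	CS	0.5pct	3.05e+01	2.88e+01	5.09e+01
NET	IDH	21pct	2.49e+01	2.42e+01	2.53e+01
NET	IDH	0.5pct	1.01e+01	8.75e+00	1.41e+01
NET	OGDH	21pct	4.19e+01	4.01e+01	4.25e+01
NET	OGDH	0.5pct	1.10e+01	7.87e+00	2.02e+01
NET	SDH	21pct	4.19e+01	4.01e+01	4.25e+01
NET	SDH	0.5pct	1.10e+01	7.87e+00	2.02e+01
NET	FH	21pct	4.19e+01	4.01e+01	4.25e+01
NET	FH	0.5pct	1.10e+01	7.87e+00	2.02e+01
NET	MDH	21pct	1.17e+02	1.08e+02	1.24e+02
NET	MDH	0.5pct	3.14e+01	2.62e+01	5.70e+01
NET	GOT	21pct	8.11e+00	8.06e+00	8.23e+00
NET	GOT	0.5pct	4.98e+00	4.32e+00	5.64e+00
NET	PST	21pct	1.95e+00	1.63e+00	2.00e+00
NET	PST	0.5pct	2.42e-01	1.34e-01	3.57e+01
NET	SHT	21pct	6.38e+00	6.22e+00	6.43e+00
NET	SHT	0.5pct	3.91e+00	3.71e+00	4.10e+00
NET	CYST	21pct	-7.12e+00	-7.19e+00	-6.81e+00
NET	CYST	0.5pct	-2.10e+00	-2.97e+00	-1.44e+00
NET	SD	21pct	1.17e+01	1.04e+01	1.20e+01
NET	SD	0.5pct	2.82e-01	0.00e+00	1.47e+00
NET	GLYS	21pct	3.39e+00	3.35e+00	3.49e+00
NET	GLYS	0.5pct	1.80e+00	1.66e+00	1.93e+00
NET	BIOMASS	21pct	2.38e-02	2.34e-02	2.39e-02
NET	BIOMASS	0.5pct	1.68e-02	1.61e-02	1.75e-02
NET	ACL	21pct	7.74e+01	6.29e+01	1.04e+02
NET	ACL	0.5pct	2.04e+01	1.95e+01	3.71e+01
NET	LIPS	21pct	4.84e+01	4.55e+01	4.84e+01
NET	LIPS	0.5pct	1.00e-07	0.00e+00	1.68e+01
NET	cPYR	21pct	1.00e+00	8.47e-01	1.00e+00
NET	cPYR	0.5pct	1.42e-01	0.00e+00	1.00e+00
NET	mPYR	21pct	1.00e-07	0.00e+00	1.53e-01
NET	mPYR	0.5pct	8.58e-01	0.00e+00	1.00e+00
NET	sPYR	21pct	1.00e+00	1.00e+00	1.00e+00
NET	sPYR	0.5pct	1.00e+00	1.00e+00	1.00e+00
EXCH	MCT	21pct	1.00e-07	0.00e+00	1.05e-01
EXCH	MCT	0.5pct	1.52e+03	1.35e+03	2.41e+03
EXCH	GLUR	21pct	5.10e+00	4.77e+00	5.23e+00
EXCH	GLUR	0.5pct	1.54e+00	1.11e+00	2.54e+00
EXCH	PGI	21pct	2.78e+05	1.77e+05	Inf
EXCH	PGI	0.5pct	2.46e+05	0.00e+00	Inf
EXCH	ALDO	21pct	1.43e+02	1.43e+02	1.43e+02
EXCH	ALDO	0.5pct	3.20e+02	2.79e+02	3.60e+02
EXCH	TPI	21pct	4.33e+03	4.33e+03	1.09e+04
EXCH	TPI	0.5pct	1.70e+03	1.06e+03	3.06e+03
EXCH	GAPDH	21pct	4.42e+02	4.72e+00	4.50e+02
EXCH	GAPDH	0.5pct	1.00e-07	0.00e+00	2.39e+02
EXCH	LDH	21pct	1.63e+03	1.62e+03	1.80e+03
EXCH	LDH	0.5pct	4.80e+00	0.00e+00	3.51e+02
EXCH	GPT1	21pct	1.00e-07	0.00e+00	2.61e-01
EXCH	GPT1	0.5pct	8.32e+02	0.00e+00	9.06e+02
EXCH	GPT2	21pct	4.21e-04	0.00e+00	2.92e+00
EXCH	GPT2	0.5pct	1.28e-04	0.00e+00	NA
EXCH	TK1	21pct	9.97e+04	6.27e+03	Inf
EXCH	TK1	0.5pct	1.47e+02	6.67e+01	2.60e+02
EXCH	TA	21pct	5.93e+00	5.79e+00	6.97e+00
EXCH	TA	0.5pct	2.35e-04	0.00e+00	7.54e+00
EXCH	TK2	21pct	1.00e+07	-Inf	Inf
EXCH	TK2	0.5pct	9.05e+00	4.10e+00	1.43e+01
EXCH	GLDH	21pct	1.52e+03	1.52e+03	7.13e+03
EXCH	GLDH	0.5pct	3.78e+02	1.93e+02	1.94e+03
EXCH	GLS	21pct	3.99e-01	0.00e+00	8.04e-01
EXCH	GLS	0.5pct	1.00e-07	0.00e+00	3.84e-01
EXCH	IDH	21pct	4.55e+00	4.03e+00	5.19e+00
EXCH	IDH	0.5pct	2.52e+00	1.80e+00	4.50e+00
EXCH	SDH	21pct	1.22e+03	NA	Inf
EXCH	SDH	0.5pct	7.60e+01	2.57e+01	Inf
EXCH	FH	21pct	3.66e+05	1.95e+05	Inf
EXCH	FH	0.5pct	5.05e+05	3.06e+02	Inf
EXCH	MDH	21pct	1.11e+03	7.88e+02	2.38e+03
EXCH	MDH	0.5pct	1.33e+02	7.22e+01	3.25e+02
EXCH	GOT	21pct	1.00e+07	-Inf	Inf
EXCH	GOT	0.5pct	4.42e+01	0.00e+00	Inf
EXCH	SHT	21pct	5.10e+00	8.92e-01	5.25e+00
EXCH	SHT	0.5pct	6.07e-07	0.00e+00	3.32e+02
EXCH	CYST	21pct	1.52e-05	0.00e+00	2.55e-04
EXCH	CYST	0.5pct	1.46e-02	0.00e+00	Inf
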