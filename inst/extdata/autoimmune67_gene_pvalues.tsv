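gene	metacca_p	CEL	IBD	MS	PBC	RA	SLE	T1D
ADAD1	1.05E-30	1.00E-06	1.00E-06	0.29	1.23E-02	1.10E-05	2.58E-02	6.97E-03
ADCY5	1.44E-06	2.40E-02	3.91E-02	1.00E-06	3.75E-02	1.29E-02	1.32E-02	0.87
AHI1	2.03E-87	5.05E-02	0.30	1.00E-06	0.36	0.54	1.94E-03	4.75E-02
ATG5	1.53E-16	0.33	7.00E-06	0.53	1.87E-03	1.54E-03	1.00E-06	0.94
C1orf106	1.82E-33	0.09	3.09E-02	7.79E-02	1.22E-02	1.00E-06	5.30E-05	3.73E-02
C1orf141	7.70E-11	0.44	1.00E-06	0.87	1.00E-06	9.85E-03	2.93E-03	0.53
C5orf56	1.87E-16	2.07E-03	1.00E-06	0.29	0.67	9.41E-02	1.86E-02	6.48E-02
CALU	2.10E-10	0.20	1.75E-02	2.21E-02	1.00E-06	1.00E-06	1.00E-06	7.18E-02
CCDC136	3.51E-25	0.030	2.90E-02	0.38	1.00E-06	1.00E-05	1.00E-06	0.39
CD58	5.43E-13	0.520	2.44E-02	0.158	0.71	1.00E-06	0.60	6.64E-02
CIITA	4.85E-28	4.05E-03	0.21	1.00E-06	1.00E-06	0.54	1.47E-04	1.00E-06
CLEC16A	9.26E-85	1.28E-02	2.12E-03	1.00E-06	1.00E-06	0.62	1.00E-06	1.00E-06
CUL2	2.56E-19	0.40	1.00E-06	0.39	2.91E-02	0.78	4.12E-04	5.76E-02
CUX2	2.28E-34	0.45	7.00E-06	0.119	2.60E-03	3.06E-02	0.12	1.00E-06
DEAF1	7.99E-14	0.40	9.22E-02	0.85	9.31E-02	0.86	1.00E-06	0.42
DGKQ	1.61E-15	0.88	0.43	2.18E-03	1.00E-06	9.95E-02	4.57E-03	0.32
DNMT1	6.97E-07	0.39	6.87E-04	7.82E-04	2.00E-06	5.03E-04	1.00E-06	9.33E-02
EFR3B	1.70E-99	0.34	1.00E-06	2.72E-02	1.00E-06	2.78E-03	0.47	1.54E-02
ERAP2	1.77E-49	0.98	1.00E-06	0.25	6.88E-04	0.45	0.57	4.76E-02
EVI5	4.08E-19	0.39	0.23	1.00E-06	0.65	1.18E-02	0.23	1.50E-02
FGF2	1.78E-08	1.00E-06	1.00E-06	9.08E-03	0.39	3.04E-03	0.18	1.40E-05
FYCO1	2.73E-11	1.00E-06	2.45E-02	1.00E-02	0.74	0.49	0.57	0.86
GRIP1	2.20E-62	1.39E-02	1.00E-06	0.20	0.25	0.25	4.43E-02	0.73
HNF1B	2.17E-10	0.14	5.60E-03	0.44	0.11	2.94E-02	0.31	1.00E-06
IKZF1	4.37E-10	0.02	0.42	7.70E-02	0.29	4.02E-04	0.49	1.00E-06
IKZF3	2.57E-203	0.41	1.00E-06	9.31E-02	0.47	0.43	0.54	2.63E-02
IL22RA2	1.55E-11	0.19	0.46	1.00E-06	2.85E-03	0.67	3.28E-02	0.12
IL23R	1.00E-232	0.90	1.00E-06	0.45	1.00E-06	0.11	8.16E-02	0.91
INPP1	3.40E-06	0.35	0.25	0.695	4.30E-05	3.65E-03	1.00E-06	0.56
IRF1	6.56E-72	9.87E-03	1.00E-06	4.58E-02	0.42	3.38E-02	0.53	5.98E-02
ITGAM	2.41E-48	5.22E-02	0.80	7.03E-02	0.17	0.20	1.00E-06	0.23
JAK2	6.34E-118	0.18	1.00E-06	2.21E-03	0.63	0.40	8.33E-02	0.53
KIAA1109	5.27E-16	2.00E-06	1.00E-05	1.79E-03	0.12	4.27E-02	0.35	1.00E-06
LINC00271	1.22E-08	1.63E-02	0.97	1.00E-06	0.48	0.26	1.16E-03	1.78E-03
LOC101927051	5.60E-11	0.55	1.00E-06	0.13	1.00E-06	3.00E-06	4.24E-04	4.84E-03
LOC285626	3.83E-97	0.50	1.00E-06	5.05E-02	0.40	0.74	0.94	0.51
LTF	5.48E-09	1.00E-06	0.17	0.33	0.76	5.55E-02	0.93	1.51E-04
MACROD2	9.46E-07	0.35	4.60E-05	2.91E-02	1.00E-06	6.85E-03	0.12	1.88E-02
MAGI3	7.55E-24	0.65	1.10E-02	0.27	0.81	1.00E-06	8.90E-05	1.00E-06
MAP3K7	2.77E-66	0.30	1.00E-06	0.31	7.85E-02	0.25	0.48	0.46
MAP4K4	3.30E-24	1.00E-06	1.00E-06	0.15	5.08E-02	0.73	9.30E-03	7.47E-02
MPZL3	5.37E-09	1.45E-02	0.86	6.22E-04	1.00E-06	1.00E-06	1.45E-03	0.18
MST1R	3.72E-37	0.93	1.00E-06	0.56	0.4588	0.84	1.27E-02	5.08E-02
NSD1	1.16E-25	0.55	1.00E-06	1.00E-05	0.16	1.42E-02	0.55	1.44E-02
PAPOLG	7.00E-08	4.00E-06	1.00E-06	1.07E-02	0.11	1.00E-06	4.40E-02	0.50
PLCL2	2.97E-17	0.18	0.22	1.50E-02	3.00E-06	1.00E-06	0.62	0.72
PRKAA1	4.54E-18	0.12	1.00E-06	3.90E-02	0.371	0.34	0.12	0.30
PTPN2	1.06E-09	6.00E-06	1.00E-06	7.66E-03	9.56E-02	1.00E-06	0.15	1.00E-06
PUS10	5.93E-101	7.00E-06	1.00E-06	1.60E-02	0.40	0.20	0.16	7.89E-02
RBM17	2.49E-25	0.252	3.36E-02	3.10E-05	0.64	1.00E-06	0.47	1.00E-06
RNASET2	1.22E-08	0.162	1.00E-06	0.99	4.08E-04	1.77E-02	8.93E-02	0.24
SH3BP1	5.60E-11	0.562	1.00E-06	0.11	1.00E-06	3.00E-06	4.39E-04	4.35E-03
SHISA5	5.12E-118	3.68E-02	1.00E-06	0.32	0.70	0.60	0.46	0.14
SLC26A4	1.29E-35	0.90	1.00E-06	2.79E-02	0.17	0.90	0.23	9.07E-02
THADA	9.70E-149	0.48	1.00E-06	0.30	0.51	0.83	4.70E-02	2.17E-03
TNFAIP3	6.86E-33	0.48	0.38	1.99E-04	2.60E-03	9.00E-06	1.00E-06	5.88E-02
TNIK	3.66E-54	1.00E-06	0.198	5.73E-04	8.17E-02	0.34	2.71E-03	8.36E-02
TNIP1	3.52E-34	0.12	0.158	0.49	4.82E-04	9.01E-04	1.00E-06	0.39
TNS1	1.56E-18	0.11	1.00E-06	0.64	3.03E-02	8.87E-02	0.88	2.76E-02
TP63	1.05E-26	1.00E-06	2.00E-06	2.85E-02	0.33	0.68	0.25	7.99E-02
TRPV4	2.37E-09	3.43E-04	3.74E-02	0.15	1.46E-03	1.13E-03	0.25	1.00E-06
TTC34	1.98E-09	5.60E-05	1.19E-02	1.00E-06	4.60E-05	1.30E-04	4.65E-02	0.46
TYK2	1.06E-06	0.11	1.00E-06	3.00E-06	2.80E-05	5.00E-06	7.00E-06	3.82E-03
USP34	9.72E-217	4.00E-06	1.00E-06	4.59E-02	0.38	1.15E-02	0.40	0.35
WDR78	4.90E-52	2.04E-03	1.00E-06	0.12	8.53E-03	1.30E-02	0.85	0.76
WNT11	4.60E-19	0.19	1.00E-06	0.83	0.19	0.33	0.47	0.45
ZNF365	1.41E-164	0.25	1.00E-06	0.16	0.55	0.12	4.37E-02	0.36
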