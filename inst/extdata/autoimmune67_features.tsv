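gene	chrom	n_snps	r	metacca_p	gene_type
ADAD1	4	3	0.08	1.05E-30	Confirmed
ADCY5	3	11	0.05	1.44E-06	Novel
AHI1	6	13	0.12	2.03E-87	Confirmed
ATG5	6	19	0.05	1.53E-16	Confirmed
C1orf106	1	14	0.08	1.82E-33	Confirmed
C1orf141	1	1	0.05	7.70E-11	Novel
C5orf56	5	12	0.06	1.87E-16	Novel
CALU	7	6	0.05	2.10E-10	Novel
CCDC136	7	2	0.08	3.51E-25	Novel
CD58	1	8	0.05	5.43E-13	Confirmed
CIITA	16	8	0.07	4.85E-28	Confirmed
CLEC16A	16	47	0.10	9.26E-85	Confirmed
CUL2	10	9	0.06	2.56E-19	Novel
CUX2	12	42	0.08	2.28E-34	Novel
DEAF1	11	9	0.05	7.99E-14	Novel
DGKQ	4	1	0.05	1.61E-15	Novel
DNMT1	19	10	0.04	6.97E-07	Novel
EFR3B	2	11	0.13	1.70E-99	Novel
ERAP2	5	11	0.09	1.77E-49	Confirmed
EVI5	1	15	0.06	4.08E-19	Novel
FGF2	4	13	0.06	1.78E-08	Novel
FYCO1	3	6	0.05	2.73E-11	Novel
GRIP1	12	67	0.12	2.20E-62	Novel
HNF1B	17	4	0.06	2.17E-10	Novel
IKZF1	7	17	0.05	4.37E-10	Confirmed
IKZF3	17	2	0.18	2.57E-203	Confirmed
IL22RA2	6	3	0.04	1.55E-11	Novel
IL23R	1	9	0.23	1.00E-232	Confirmed
INPP1	2	1	0.04	3.40E-06	Novel
IRF1	5	1	0.11	6.56E-72	Confirmed
ITGAM	16	8	0.09	2.41E-48	Novel
JAK2	9	11	0.14	6.34E-118	Confirmed
KIAA1109	4	24	0.05	5.27E-16	Confirmed
LINC00271	6	9	0.04	1.22E-08	Novel
LOC101927051	22	8	0.05	5.60E-11	Novel
LOC285626	5	2	0.12	3.83E-97	Novel
LTF	3	5	0.04	5.48E-09	Novel
MACROD2	20	15	0.04	9.46E-07	Novel
MAGI3	1	18	0.06	7.55E-24	Confirmed
MAP3K7	6	2	0.11	2.77E-66	Confirmed
MAP4K4	2	32	0.07	3.30E-24	Novel
MPZL3	11	2	0.04	5.37E-09	Novel
MST1R	3	1	0.08	3.72E-37	Confirmed
NSD1	5	9	0.07	1.16E-25	Novel
PAPOLG	2	5	0.04	7.00E-08	Novel
PLCL2	3	23	0.05	2.97E-17	Confirmed
PRKAA1	5	3	0.06	4.54E-18	Novel
PTPN2	18	11	0.05	1.06E-09	Confirmed
PUS10	2	10	0.13	5.93E-101	Confirmed
RBM17	10	5	0.06	2.49E-25	Novel
RNASET2	6	2	0.04	1.22E-08	Confirmed
SH3BP1	22	8	0.05	5.60E-11	Novel
SHISA5	3	2	0.14	5.12E-118	Novel
SLC26A4	7	2	0.08	1.29E-35	Novel
THADA	2	50	0.15	9.70E-149	Confirmed
TNFAIP3	6	2	0.08	6.86E-33	Confirmed
TNIK	3	44	0.11	3.66E-54	Novel
TNIP1	5	23	0.07	3.52E-34	Confirmed
TNS1	2	11	0.07	1.56E-18	Novel
TP63	3	31	0.07	1.05E-26	Novel
TRPV4	12	11	0.04	2.37E-09	Confirmed
TTC34	1	2	0.04	1.98E-09	Confirmed
TYK2	19	5	0.04	1.06E-06	Confirmed
USP34	2	11	0.18	9.72E-217	Novel
WDR78	1	13	0.10	4.90E-52	Novel
WNT11	11	3	0.06	4.60E-19	Novel
ZNF365	10	39	0.17	1.41E-164	Novel
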