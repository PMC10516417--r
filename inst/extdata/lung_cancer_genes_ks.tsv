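gene	chr	n_sites	prior_p_discovery	p_discovery	prior_p_replication	p_replication
CTSL	9	25	1.32E-03	4.87E-05	8.43E-01	2.75E-03
TBX4	17	37	1.48E-03	6.49E-05	9.67E-01	9.96E-01
RASL10B	17	53	4.05E-04	6.75E-05	1.00E+00	9.81E-01
MUC3A	7	94	1.30E-04	7.33E-05	5.95E-01	6.42E-01
AMN	14	22	1.68E-04	8.08E-05	9.07E-01	9.71E-01
KRTAP19-4	21	21	3.38E-05	1.27E-04	8.74E-02	8.76E-02
KRTAP19-5	21	20	3.38E-05	1.28E-04	NA	NA
CPB2	13	25	1.74E-03	1.46E-04	1.00E+00	6.71E-01
C8orf44	8	38	1.11E-02	2.17E-04	6.74E-01	1.82E-01
ZW10	11	48	6.49E-04	2.23E-04	8.79E-01	7.19E-01
INHA	2	68	1.05E-04	2.51E-04	1.00E+00	9.04E-01
DGKB	7	79	3.33E-02	3.27E-04	9.73E-01	9.34E-01
FBXO6	1	55	2.09E-03	3.34E-04	3.47E-01	3.51E-01
PHF12	17	82	2.00E-03	3.57E-04	1.00E+00	8.35E-01
LEMD3	12	46	8.70E-04	3.58E-04	1.00E+00	9.98E-01
OR5AC2	3	70	1.09E-04	3.85E-04	1.00E+00	1.00E+00
FGF8	10	38	9.89E-02	4.52E-04	9.93E-01	7.29E-01
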