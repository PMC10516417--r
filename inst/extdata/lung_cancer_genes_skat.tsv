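gene	chr	n_sites	prior_p_discovery	p_discovery	prior_p_replication	p_replication
VAV2	9	121	3.09E-04	1.95E-05	6.72E-01	5.72E-01
DENND4B	1	69	2.21E-05	4.31E-05	9.96E-01	6.35E-01
TBX4	17	37	1.95E-03	8.41E-05	8.21E-01	9.41E-01
RHBDL3	17	27	9.09E-03	1.06E-04	1.63E-01	2.91E-01
C8orf44	8	38	5.89E-03	1.19E-04	9.97E-01	2.52E-01
CCT8	21	46	2.43E-02	2.41E-04	9.87E-01	9.99E-01
SIGLEC11	19	24	3.10E-03	2.46E-04	7.23E-01	5.81E-01
APOE	19	25	2.65E-04	2.56E-04	6.10E-03	4.01E-03
POMK	8	33	3.00E-02	3.27E-04	9.54E-01	7.50E-01
DGKB	7	79	4.34E-02	4.20E-04	3.79E-01	5.10E-01
CTSL	9	25	1.29E-02	4.30E-04	3.08E-03	1.31E-05
CPB2	13	25	5.55E-03	4.42E-04	2.98E-01	2.65E-01
ITGB6	2	61	3.23E-02	4.93E-04	9.83E-01	9.40E-01
VCPIP1	8	39	1.73E-02	4.94E-04	8.73E-01	7.00E-01
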