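gene	log2fc	padj
CG3739	0.20	2.38E-01
CG18609	0.56	4.94E-04
CG34180	0.50	1.04E-01
CG10960	0.51	4.81E-03
CG11741	0.67	3.26E-02
b6	0.38	1.79E-01
Uro	0.57	3.79E-02
rost	0.35	1.14E-01
CG4607	0.58	1.96E-04
CG15096	0.48	4.42E-02
CG9459	0.71	1.34E-03
CG14464	0.46	1.09E-02
CG5804	-0.36	1.68E-01
CG5767	-0.65	6.97E-03
CG34330	-0.22	2.57E-01
AsnS	-0.36	8.08E-02
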