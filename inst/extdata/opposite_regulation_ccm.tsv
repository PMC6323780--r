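gene	log2fc	padj
CG3739	-0.90	3.70E-13
CG18609	-0.80	7.72E-13
CG34180	-0.75	1.46E-03
CG10960	-0.67	1.49E-06
CG11741	-0.56	4.57E-02
b6	-0.55	4.23E-02
Uro	-0.54	2.75E-02
rost	-0.51	2.96E-02
CG4607	-0.48	7.35E-03
CG15096	-0.46	9.90E-02
CG9459	-0.35	8.04E-02
CG14464	-0.33	9.77E-02
CG5804	0.51	7.70E-03
CG5767	0.45	4.87E-02
CG34330	0.41	3.14E-02
AsnS	0.37	7.58E-02
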