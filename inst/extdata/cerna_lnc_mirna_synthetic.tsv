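lncRNA	miRNA	correlation	binding
ENST00000456355	miR-3173-5p	0.95	0.06
ENST00000456355	miR-938	0.93	0.05
ENST00000456355	miR-4704-3p	0.97	0.08
ENST00000456355	miR-1265	0.92	0.045
ENST00000456355	miR-644a	0.96	0.07
ENST00000456355	miR-9999	0.85	0.06
ENST00000456355	miR-8888	0.95	0.03
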