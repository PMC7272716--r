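miRNA	mRNA	context
miR-3173-5p	LY6K	-0.35
miR-3173-5p	GSDMD	-0.28
miR-938	MSRB3	-0.41
miR-938	FOSL1	-0.1
miR-4704-3p	MCAM	-0.31
miR-4704-3p	FOSL1	-0.22
miR-1265	ST6GALNAC3	-0.27
miR-644a	LY6K	-0.33
miR-644a	ABCB1	-0.5
miR-9999	MCAM	-0.4
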