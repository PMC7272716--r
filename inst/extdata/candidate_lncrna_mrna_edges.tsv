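lncRNA	alias	fold_change	p_value	level	mRNA	r
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	ZNF215	-0.99996
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	ZCCHC11	-0.99998
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	TP53I11	0.999956
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	TMEM200A	-0.999985
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	TMEM106A	-0.999953
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	SRPX	-0.999975
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	RAB3B	-0.999951
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	NDN	-0.99998
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	MLC1	-0.999973
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	GRHL2	-0.99996
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	GPC5	-0.999953
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	GDA	-0.999962
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	CHRFAM7A	-0.999962
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	CALD1	-0.99997
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	CA12	-0.999957
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	BSPRY	-0.999956
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	ADRB2	-0.999954
ENST00000422749	DSCAM-AS1:2	-281.293	3.70E-05	DOWN	ADAMTS6	-0.999972
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	ZCCHC11	0.999978
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	TP53I11	-0.999961
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	TMEM200A	0.999963
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	TMEM106A	0.999986
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	SRPX	0.999956
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	S1PR1	0.99998
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	PSG8	0.999971
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	NDN	0.999989
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	MLC1	0.999981
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	KRTAP2-3	0.999948
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	GDA	0.999959
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	CHRFAM7A	0.999962
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	CD274	0.999957
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	CALD1	0.999954
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	BSPRY	-0.999964
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	BATF	-0.999951
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	ARHGAP40	0.999979
NONHSAT057283	lnc-MPPE1-13	13.59	0.00076	UP	ADRB2	0.999951
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	TMEM200B	0.999954
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	TBX18	0.999978
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	ST6GALNAC3	0.999984
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	SNURF	0.999966
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	SNRPN	0.999982
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	PRLR	-0.999955
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	NNMT	0.999974
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	MSRB3	0.99996
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	MSN	0.99997
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	MCAM	0.999991
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	LY6K	0.999974
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	LAMC3	0.999994
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	GSDMD	0.999986
ENST00000456355	lnc-TRDMT1-5	60.836	0.00022	UP	FOSL1	0.999984
ENST00000455354	DSCAM-AS1:5	-1394.049	3.4E-05	DOWN	SLC7A2	0.999956
ENST00000455354	DSCAM-AS1:5	-1394.049	3.4E-05	DOWN	S1PR1	-0.999981
ENST00000455354	DSCAM-AS1:5	-1394.049	3.4E-05	DOWN	OSBPL3	-0.999963
ENST00000455354	DSCAM-AS1:5	-1394.049	3.4E-05	DOWN	NDN	-0.999972
ENST00000455354	DSCAM-AS1:5	-1394.049	3.4E-05	DOWN	GPC5	-0.999974
ENST00000455354	DSCAM-AS1:5	-1394.049	3.4E-05	DOWN	CXCL12	0.999957
ENST00000455354	DSCAM-AS1:5	-1394.049	3.4E-05	DOWN	CHRFAM7A	-0.999951
ENST00000455354	DSCAM-AS1:5	-1394.049	3.4E-05	DOWN	BSPRY	0.999960
ENST00000594783	ZNF667-AS1	109.815	0.00011	UP	THSD1	0.999953
ENST00000594783	ZNF667-AS1	109.815	0.00011	UP	SAMD3	0.999954
ENST00000594783	ZNF667-AS1	109.815	0.00011	UP	PSMB8	0.999981
ENST00000594783	ZNF667-AS1	109.815	0.00011	UP	LAMC2	0.999971
ENST00000594783	ZNF667-AS1	109.815	0.00011	UP	IGFBP3	0.999962
ENST00000594783	ZNF667-AS1	109.815	0.00011	UP	ADRB2	0.999951
NONHSAT097797	lnc-CFI-3	-537.10388	4.3E-05	DOWN	ZCCHC11	-0.999963
NONHSAT097797	lnc-CFI-3	-537.10388	4.3E-05	DOWN	NDN	-0.999949
NONHSAT097797	lnc-CFI-3	-537.10388	4.3E-05	DOWN	MLC1	-0.999965
NONHSAT097797	lnc-CFI-3	-537.10388	4.3E-05	DOWN	CDH1	0.999954
NONHSAT097797	lnc-CFI-3	-537.10388	4.3E-05	DOWN	CA12	0.999994
NONHSAT097797	lnc-CFI-3	-537.10388	4.3E-05	DOWN	C5AR2	0.999978
NONHSAT097797	lnc-CFI-3	-537.10388	4.3E-05	DOWN	BSPRY	0.999986
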