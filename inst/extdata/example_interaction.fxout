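FoldX interaction energy analysis
Output type: AnalyseComplex

Pdb	Group1	Group2	IntraclashesGroup1	IntraclashesGroup2	Interaction Energy	Backbone Hbond
./complex.pdb	A	B	0.52	0.31	-12.34	-3.10
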