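FoldX energy difference upon mutation

Pdb	total energy	Backbone Hbond	Sidechain Hbond
complex_Repair.pdb	1.87	0.10	-0.22
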