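id	label
Gene	Gene
Regulatory Gene	Regulatory Gene
MicroRNA Gene	MicroRNA Gene
MIR1243 Gene	MIR1243 Gene
Antigen Gene	Antigen Gene
GAGE Gene	GAGE Gene
GAGE6 Gene	GAGE6 Gene
CAGE1 Gene	CAGE1 Gene
GAGE6 wt Allele	GAGE6 wt Allele
CAGE1 wt Allele	CAGE1 wt Allele
CAGE1 Mutant Allele	CAGE1 Mutant Allele
CAGE1 Polymorphic Allele	CAGE1 Polymorphic Allele
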