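child_id	parent_id
Regulatory Gene	Gene
MicroRNA Gene	Gene
MIR1243 Gene	MicroRNA Gene
Antigen Gene	Regulatory Gene
GAGE Gene	Antigen Gene
GAGE6 Gene	GAGE Gene
CAGE1 Gene	Antigen Gene
GAGE6 wt Allele	GAGE6 Gene
CAGE1 wt Allele	CAGE1 Gene
CAGE1 Mutant Allele	CAGE1 wt Allele
CAGE1 Polymorphic Allele	CAGE1 wt Allele
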