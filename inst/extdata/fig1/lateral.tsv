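source_id	rel_type	target_id
MicroRNA Gene	Gene Found In Organism	Human
MIR1243 Gene	Gene Found In Organism	Human
Antigen Gene	Gene Plays Role In Process	Immune Response Process
GAGE Gene	Gene Plays Role In Process	Immune Response Process
GAGE6 Gene	Gene Plays Role In Process	Immune Response Process
CAGE1 Gene	Gene Plays Role In Process	Immune Response Process
GAGE6 wt Allele	Gene Plays Role In Process	Immune Response Process
CAGE1 wt Allele	Gene Plays Role In Process	Immune Response Process
CAGE1 Mutant Allele	Gene Plays Role In Process	Immune Response Process
CAGE1 Polymorphic Allele	Gene Plays Role In Process	Immune Response Process
GAGE6 wt Allele	Gene Found In Organism	Human
CAGE1 wt Allele	Gene Found In Organism	Human
CAGE1 Mutant Allele	Gene Found In Organism	Human
CAGE1 Polymorphic Allele	Gene Found In Organism	Human
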