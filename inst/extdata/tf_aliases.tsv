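alias	symbol
ERA	ESR1
ER-ALPHA	ESR1
ERALPHA	ESR1
HNF4ALPHA	HNF4A
HNF4A_NR	HNF4A
FRA2	FOSL2
FRA-2	FOSL2
CEBPBETA	CEBPB
AP2ALPHA	TFAP2A
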