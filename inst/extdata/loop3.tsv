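id	equation	lb	ub	reversible	exchange	biomass
EX_A	A ->	-10	1000	FALSE	TRUE	FALSE
R_AB	A -> B	-1000	1000	TRUE	FALSE	FALSE
R_BC	B -> C	-1000	1000	TRUE	FALSE	FALSE
R_CA	C -> A	-1000	1000	TRUE	FALSE	FALSE
EX_C	C ->	0	1000	FALSE	TRUE	FALSE
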