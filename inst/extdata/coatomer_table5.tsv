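# Coatomer (COPI, COPII, clathrin/adaptin) component presence/absence across 46 eukaryote genomes
component	annotation	Am	Dm	Hs	Mm	Rn	Gg	Bt	Xl	Dr	Ci	Ce	Mb	Sc	Ps	Cg	Ca	Dh	Yl	Nc	An	Sp	Um	Cn	Ec	Eh	Dd	Cm	Vc	Ot	Cr	Pp	Os	At	Tt	Ptr	Pi	Tps	Tp	Ch	Tg	Pf	Pb	Gl	Ng	Tv	Li
COPI-alpha	COPI	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
COPI-beta	COPI	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
COPI-beta-prime	COPI		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
COPI-gamma	COPI	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x
COPI-delta	COPI	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
COPI-epsilon	COPI	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x		x	x	x	x	x	x	x	x	x	x	x	x	x			x				x	x	x
COPI-zeta	COPI	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
sar1	COPII	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
sec16	COPII	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x						x	x	x	x	x		x	x								x		
sec23	COPII	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
sec24	COPII	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
sec31	COPII	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
sfb3	COPII	x	x	x	x	x	x	x	x	x	x		x	x		x	x	x	x	x	x	x	x		x	x	x				x	x	x	x													
chc1	Clathrin/adaptin	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
clc1	Clathrin/adaptin	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x			x		x	x	x	x	x	x	x	x	x	x			x				x	x	x
apl1	Clathrin/adaptin			x	x	x	x	x	x	x				x	x	x	x	x	x	x	x	x		x																							
apl2	Clathrin/adaptin		x	x	x	x		x	x	x	x	x		x	x	x	x	x	x	x			x		x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
apl3	Clathrin/adaptin	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x		x	x	x	x	x	x	x	x	x	x	x			x	x	x	x	x	x
apl4	Clathrin/adaptin		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x		x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x
apl5	Clathrin/adaptin	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x		x		x	x	x		x	x	x			x				x	x	x
apl6	Clathrin/adaptin	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x			x		x	x	x		x	x	x			x	x	x		x	x	x
apm1	Clathrin/adaptin	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x
apm3	Clathrin/adaptin	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x			x		x	x	x	x	x	x	x		x	x			x	x	x	x
apm4	Clathrin/adaptin	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x		x	x	x	x	x	x	x	x	x	x			x	x	x	x	x	x	x
aps1	Clathrin/adaptin	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x		x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x		x	x	x
aps2	Clathrin/adaptin	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x		x	x		x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x
aps3	Clathrin/adaptin	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x		x	x	x		x	x	x			x	x	x		x	x	x
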