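# Candidate nucleoporin presence/absence across 51 eukaryote genomes (published HMM-profile screen)
component	annotation	Ag	Am	Dm	Hs	Mm	Rn	Gg	Xl	Dr	Tn	Ci	Ce	Mb	Sc	Kl	Ps	Cg	Ca	Dh	Yl	Nc	Gz	An	Mg	Sp	Um	Cn	Ec	Eh	Dd	Cm	Vc	Ot	Cr	Pp	Pt	Os	At	Tt	Ptr	Pi	Tps	Tp	Ch	Tg	Pb	Gl	Ng	Tv	Tb	Lm
Gle1	Cytoplasmic fibrils	x	x	x	x	x	x	x		x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x	x		x	x	x	x	x	x		x	x	x		x				x			
Aladin	Cytoplasmic fibrils	x		x	x	x	x	x	x	x	x	x		x																	x	x	x	x		x	x	x	x			x							x		x	x
Nup88	Cytoplasmic fibrils	x	x	x	x	x	x	x	x	x	x	x			x	x	x	x	x	x	x	x	x	x	x	x	x	x			x	x	x	x	x	x	x	x	x			x										
Nup214	Cytoplasmic fibrils	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x			x			x	x	x			x				x			x			x
Nup358	Cytoplasmic fibrils	x	x	x	x	x	x	x	x	x	x	x	x	x																																						
Nup160	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x		x	x		x	x	x	x			x							x			
Nup133	Scaffold	x	x	x	x	x	x	x		x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x			x	x	x	x	x	x	x	x	x		x	x	x						x			
Nup107	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x	x	x	x		x	x	x	x		x	x	x					x	x	x	x	x
Nup75	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x		x	x	x	x	x	x	x			x							x			
Nup43	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x																	x					x	x	x	x			x										
Nup37	Scaffold	x	x	x	x	x	x	x	x	x	x	x									x	x	x	x	x	x																										
Seh1	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x		x		x			x	x	x	x	x	x	x	x	x	x	x	x							x		x	x
Sec13	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x
Nup205	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x					x	x	x	x	x	x	x			x							x	x	x	x
Nup188	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x			x		x	x	x	x	x	x	x													
Nup155	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x	x	x	x	x	x	x	x	x	x	x	x		x			x	x	x	x	x
Nup93	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x		x	x	x	x	x	x	x	x	x						x	x	x	x
Nup35	Scaffold	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x					x		x	x		x	x	x	x	x	x	x	x	x		x	x	x					x		x		
Ndc1	Transmembrane	x		x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x						x	x	x	x	x	x			x								x		
Pom121	Transmembrane				x	x	x	x	x	x	x																																									
Gp210	Transmembrane	x	x	x	x	x	x	x	x	x	x	x	x	x																x	x					x	x	x	x	x				x	x	x			x	x		
Pom152	Transmembrane														x	x	x	x	x	x	x	x	x	x	x	x	x	x																								
Pom34	Transmembrane														x	x	x	x	x	x	x	x	x	x	x	x																										
Nup96-98	Nuclear ring	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x
Rae1	Nuclear ring	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x		x	x
Nup62	Central channel	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x		x	x	x		x	x			x	x	x	x
Nup58	Central channel	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x		x		x	x	x	x	x			x							x			x
Nup54	Central channel	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x	x	x	x	x	x	x	x	x	x	x	x	x			x		x	x	x	x	x
Nup50	Nuclear basket	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x			x			x			x	x	x		x	x	x						x			
Nup153	Nuclear basket		x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x					x	x	x						x			x	x	x		x	x	x						x			
TPR	Nuclear basket	x	x	x	x	x	x	x	x	x	x	x	x	x	x	x		x	x	x	x	x	x	x	x	x	x	x			x		x	x		x	x	x	x		x	x	x						x			
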