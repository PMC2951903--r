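# Mitosis phenotype per fungal genome: ascomycetes closed, basidiomycetes and the zygomycete open
genome	phenotype	class	species
An	closed	Ascomycetes	Aspergillus nidulans
Yl	closed	Ascomycetes	Yarrowia lipolytica
Ps	closed	Ascomycetes	Pichia stipitis
Nc	closed	Ascomycetes	Neurospora crassa
Sp	closed	Ascomycetes	Schizosaccharomyces pombe
Sc	closed	Ascomycetes	Saccharomyces cerevisiae
Kl	closed	Ascomycetes	Kluyveromyces lactis
Ca	closed	Ascomycetes	Candida albicans
Cg	closed	Ascomycetes	Candida glabrata
Dh	closed	Ascomycetes	Debaryomyces hansenii
Gz	closed	Ascomycetes	Gibberella zeae
Mg	closed	Ascomycetes	Magnaporthe grisea
Cn	open	Basidiomycetes	Cryptococcus neoformans
Pc	open	Basidiomycetes	Phanerochaete chrysosporium
Um	open	Basidiomycetes	Ustilago maydis
Lb	open	Basidiomycetes	Laccaria bicolor
Cc	open	Basidiomycetes	Coprinopsis cinerea
Ml	open	Basidiomycetes	Malassezia globosa
Ro	open	Zygomycetes	Rhizopus oryzae
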