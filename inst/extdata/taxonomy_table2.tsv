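# Genome code -> taxonomic class -> supergroup for the nucleoporin survey
genome	class	supergroup	species
Ag	Dipterans	Opisthokonts	Anopheles gambiae
Am	Dipterans	Opisthokonts	Apis mellifera
Dm	Dipterans	Opisthokonts	Drosophila melanogaster
Hs	Vertebrates	Opisthokonts	Homo sapiens
Mm	Vertebrates	Opisthokonts	Mus musculus
Rn	Vertebrates	Opisthokonts	Rattus norvegicus
Gg	Vertebrates	Opisthokonts	Gallus gallus
Xl	Vertebrates	Opisthokonts	Xenopus laevis
Dr	Vertebrates	Opisthokonts	Danio rerio
Tn	Vertebrates	Opisthokonts	Tetraodon nigroviridis
Ci	Tunicates	Opisthokonts	Ciona intestinalis
Ce	Nematodes	Opisthokonts	Caenorhabditis elegans
Mb	Choanoflagellates	Opisthokonts	Monosiga brevicollis
Sc	Ascomycetes	Opisthokonts	Saccharomyces cerevisiae
Kl	Ascomycetes	Opisthokonts	Kluyveromyces lactis
Ps	Ascomycetes	Opisthokonts	Pichia stipitis
Cg	Ascomycetes	Opisthokonts	Candida glabrata
Ca	Ascomycetes	Opisthokonts	Candida albicans
Dh	Ascomycetes	Opisthokonts	Debaryomyces hansenii
Yl	Ascomycetes	Opisthokonts	Yarrowia lipolytica
Nc	Ascomycetes	Opisthokonts	Neurospora crassa
Gz	Ascomycetes	Opisthokonts	Gibberella zeae
An	Ascomycetes	Opisthokonts	Aspergillus nidulans
Mg	Ascomycetes	Opisthokonts	Magnaporthe grisea
Sp	Ascomycetes	Opisthokonts	Schizosaccharomyces pombe
Um	Basidiomycetes	Opisthokonts	Ustilago maydis
Cn	Basidiomycetes	Opisthokonts	Cryptococcus neoformans
Ec	Microsporidia	Opisthokonts	Encephalitozoon cuniculi
Eh	Amoebozoa	Amoebozoa	Entamoeba histolytica
Dd	Amoebozoa	Amoebozoa	Dictyostelium discoideum
Cm	Rhodophytes	Plantae	Cyanidioschyzon merolae
Vc	Chlorophytes	Plantae	Volvox carteri
Ot	Chlorophytes	Plantae	Ostreococcus lucimarinus
Cr	Chlorophytes	Plantae	Chlamydomonas reinhardtii
Pp	Streptophytes	Plantae	Physcomitrella patens
Pt	Streptophytes	Plantae	Populus trichocarpa
Os	Streptophytes	Plantae	Oryza sativa
At	Streptophytes	Plantae	Arabidopsis thaliana
Tt	Ciliates	Chromalveolates	Tetrahymena thermophila
Ptr	Heterokonts	Chromalveolates	Phaeodactylum tricornutum
Pi	Heterokonts	Chromalveolates	Phytophthora infestans
Tps	Heterokonts	Chromalveolates	Thalassiosira pseudonana
Tp	Apicomplexans	Chromalveolates	Theileria parva
Ch	Apicomplexans	Chromalveolates	Cryptosporidium hominis
Tg	Apicomplexans	Chromalveolates	Toxoplasma gondii
Pb	Apicomplexans	Chromalveolates	Plasmodium berghei
Gl	Diplomonads	Excavates	Giardia lamblia
Ng	Heterolobosea	Excavates	Naegleria gruberi
Tv	Parabasalids	Excavates	Trichomonas vaginalis
Tb	Kinetoplastids	Excavates	Trypanosoma brucei
Lm	Kinetoplastids	Excavates	Leishmania major
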