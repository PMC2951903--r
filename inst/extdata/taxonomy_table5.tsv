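# Genome code -> taxonomic class -> supergroup for the coatomer survey (codes scoped to this fixture)
genome	class	supergroup	species
Am	Diptera	Opisthokonts	Apis mellifera
Dm	Diptera	Opisthokonts	Drosophila melanogaster
Hs	Vertebrates	Opisthokonts	Homo sapiens
Mm	Vertebrates	Opisthokonts	Mus musculus
Rn	Vertebrates	Opisthokonts	Rattus norvegicus
Gg	Vertebrates	Opisthokonts	Gallus gallus
Bt	Vertebrates	Opisthokonts	Bos taurus
Xl	Vertebrates	Opisthokonts	Xenopus laevis
Dr	Vertebrates	Opisthokonts	Danio rerio
Ci	Tunicates	Opisthokonts	Ciona intestinalis
Ce	Nematodes	Opisthokonts	Caenorhabditis elegans
Mb	Choanoflagellates	Opisthokonts	Monosiga brevicollis
Sc	Ascomycetes	Opisthokonts	Saccharomyces cerevisiae
Ps	Ascomycetes	Opisthokonts	Pichia stipitis
Cg	Ascomycetes	Opisthokonts	Candida glabrata
Ca	Ascomycetes	Opisthokonts	Candida albicans
Dh	Ascomycetes	Opisthokonts	Debaryomyces hansenii
Yl	Ascomycetes	Opisthokonts	Yarrowia lipolytica
Nc	Ascomycetes	Opisthokonts	Neurospora crassa
An	Ascomycetes	Opisthokonts	Aspergillus nidulans
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
Os	Streptophytes	Plantae	Oryza sativa
At	Streptophytes	Plantae	Arabidopsis thaliana
Tt	Ciliates	Chromalveolates	Tetrahymena thermophila
Ptr	Heterokonts	Chromalveolates	Phaeodactylum tricornutum
Pi	Heterokonts	Chromalveolates	Phytophthora infestans
Tps	Heterokonts	Chromalveolates	Thalassiosira pseudonana
Tp	Apicomplexans	Chromalveolates	Theileria parva
Ch	Apicomplexans	Chromalveolates	Cryptosporidium hominis
Tg	Apicomplexans	Chromalveolates	Toxoplasma gondii
Pf	Apicomplexans	Chromalveolates	Plasmodium falciparum
Pb	Apicomplexans	Chromalveolates	Plasmodium berghei
Gl	Diplomonads	Excavates	Giardia lamblia
Ng	Heterolobosea	Excavates	Naegleria gruberi
Tv	Parabasalids	Excavates	Trichomonas vaginalis
Li	Kinetoplastids	Excavates	Leishmania infantum
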