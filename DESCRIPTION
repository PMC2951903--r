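Package: lecatrace
Title: Phylogenetic Profiling and Ancestral Reconstruction of Protein
    Complexes Across Eukaryote Supergroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the composition of multiprotein complexes
    (the nuclear pore complex and the COPI/COPII/clathrin coatomer
    complexes) back to the last eukaryotic common ancestor (LECA).
    Provides a desk-scale homolog screen based on position-specific
    log-odds profiles with affine gaps, together with the vetting rules
    used for nucleoporin annotation (rejection of candidates whose
    similarity is confined to FG- or WD-repeat regions, required-motif
    checks, reciprocal best-hit validation and a permissive rescue
    search); presence/absence matrix input/output with curated survey
    fixtures; Dollo parsimony reconstruction of ancestral gene content on
    rooted supergroup topologies with unrestricted-parsimony ambiguity
    flags, alternative rootings and star-tree bounds; comparative reports
    (mitosis-phenotype association, supergroup-level coatomer absences,
    cross-study comparison); and a synthetic-data generator for trees,
    single-gain/multiple-loss character evolution with detection noise,
    and proteomes with planted homologs and repeat decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
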