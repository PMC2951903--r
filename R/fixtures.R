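#' Load a curated survey fixture
#'
#' The package ships small plain-text transcriptions of published
#' presence/absence surveys and control data that anchor the test suite
#' and the worked examples:
#'
#' * `nup_table2`: candidate nucleoporins (31 components) across 51
#'   eukaryote genomes, annotated by NPC subcomplex. Returned as a
#'   [presence_matrix()] with the matching [taxonomy_map()] attached as
#'   attribute `"taxonomy"`.
#' * `taxonomy_table2`: the genome-to-class-to-supergroup map for
#'   `nup_table2`, as a [taxonomy_map()].
#' * `tbrucei_table1`: the *Trypanosoma brucei* control set comparing a
#'   proteomics-established NPC inventory with the profile screen, as a
#'   `control_reference` data frame (see [control_reference()]).
#' * `fungi_table4`: the anchoring nucleoporins Ndc1, Pom152 and Pom34
#'   across 19 fungal genomes, as a [presence_matrix()].
#' * `mitosis_phenotypes`: open/closed mitosis labels for the 19 fungal
#'   genomes, as a [phenotype_map()].
#' * `coatomer_table5`: COPI, COPII and clathrin/adaptin components (27
#'   subunits) across 46 genomes, as a [presence_matrix()] with its own
#'   taxonomy attached as attribute `"taxonomy"` (genome codes are scoped
#'   per fixture; `Pt` for instance denotes different species in the
#'   nucleoporin and coatomer surveys).
#'
#' @param name One of `"nup_table2"`, `"taxonomy_table2"`,
#'   `"tbrucei_table1"`, `"fungi_table4"`, `"mitosis_phenotypes"`,
#'   `"coatomer_table5"`.
#' @return See above; the class depends on the fixture.
#' @examples
#' m <- load_fixture("nup_table2")
#' dim(m$states)
#' @export
load_fixture <- function(name) {
  known <- c("nup_table2", "taxonomy_table2", "tbrucei_table1",
             "fungi_table4", "mitosis_phenotypes", "coatomer_table5")
  if (!is.character(name) || length(name) != 1L || !(name %in% known))
    stop("unknown fixture name; expected one of: ",
         paste(known, collapse = ", "))
  path <- function(f) system.file("extdata", f, package = "lecatrace",
                                  mustWork = TRUE)
  switch(name,
    nup_table2 = {
      m <- read_presence_matrix(path("nup_table2.tsv"))
      attr(m, "taxonomy") <- read_taxonomy_map(path("taxonomy_table2.tsv"))
      m
    },
    taxonomy_table2 = read_taxonomy_map(path("taxonomy_table2.tsv")),
    tbrucei_table1 = read_control_reference(path("tbrucei_table1.tsv")),
    fungi_table4 = read_presence_matrix(path("fungi_table4.tsv")),
    mitosis_phenotypes = read_phenotype_map(path("mitosis_phenotypes.tsv")),
    coatomer_table5 = {
      m <- read_presence_matrix(path("coatomer_table5.tsv"))
      attr(m, "taxonomy") <- read_taxonomy_map(path("taxonomy_table5.tsv"))
      m
    })
}

#' Taxonomy attached to a fixture matrix
#'
#' @param m A fixture [presence_matrix()] carrying a `"taxonomy"`
#'   attribute.
#' @return The attached [taxonomy_map()].
#' @export
fixture_taxonomy <- function(m) {
  tax <- attr(m, "taxonomy")
  if (is.null(tax)) stop("matrix carries no attached taxonomy")
  tax
}

#' Construct a control-reference table
#'
#' A control reference records, for each externally identified protein of
#' a control genome, how the profile screen treated it: `identified`
#' (accepted with a component assignment), `excluded` (hit returned but
#' removed during vetting) or `not_detected`. Exactly one status applies
#' per record; an FG-repeat note may only be attached to records that were
#' not assigned a component.
#'
#' @param protein_id External protein identifiers.
#' @param orthology_established Logical; was orthology established
#'   independently of the screen?
#' @param status One of `"identified"`, `"excluded"`, `"not_detected"` per
#'   record.
#' @param fg_repeats Logical; does the record carry an FG-repeat note?
#' @param component Assigned component name, or `NA`/empty when none.
#' @return A data frame of class `control_reference`.
#' @export
control_reference <- function(protein_id, orthology_established, status,
                              fg_repeats, component) {
  status <- as.character(status)
  if (!all(status %in% c("identified", "excluded", "not_detected")))
    stop("status must be identified, excluded or not_detected")
  component <- as.character(component)
  component[!nzchar(component) | is.na(component)] <- NA_character_
  fg_repeats <- as.logical(fg_repeats)
  if (any(fg_repeats & !is.na(component)))
    stop("FG-repeat note is only allowed on records without a component")
  structure(data.frame(protein_id = as.character(protein_id),
                       orthology_established = as.logical(orthology_established),
                       status = status, fg_repeats = fg_repeats,
                       component = component, stringsAsFactors = FALSE),
            class = c("control_reference", "data.frame"))
}

#' @noRd
read_control_reference <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  control_reference(df$protein_id, df$orthology_established == 1,
                    df$status, df$fg_repeats == 1, df$component)
}

#' Construct a phenotype map
#'
#' Maps genome codes to a mitosis phenotype; the label vocabulary is
#' closed over `open`, `closed` and `unknown`.
#'
#' @param genome Character vector of unique genome codes.
#' @param phenotype Character vector of labels in
#'   `c("open", "closed", "unknown")`.
#' @param class Optional taxonomic class labels.
#' @return A data frame of class `phenotype_map`.
#' @export
phenotype_map <- function(genome, phenotype, class = NULL) {
  phenotype <- as.character(phenotype)
  if (!all(phenotype %in% c("open", "closed", "unknown")))
    stop("phenotype labels must be open, closed or unknown")
  if (anyDuplicated(genome)) stop("duplicate genome codes in phenotype map")
  structure(data.frame(genome = as.character(genome), phenotype = phenotype,
                       class = if (is.null(class)) NA_character_
                               else as.character(class),
                       stringsAsFactors = FALSE),
            class = c("phenotype_map", "data.frame"))
}

#' @noRd
read_phenotype_map <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  phenotype_map(df$genome, df$phenotype,
                class = if ("class" %in% names(df)) df$class)
}
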