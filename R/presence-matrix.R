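#' Construct a presence/absence matrix
#'
#' The central object of the pipeline: a binary components-by-genomes
#' indicator matrix, optionally annotated with a per-component category
#' label (e.g. an NPC subcomplex or a coatomer complex).
#'
#' @param states Numeric or logical matrix coercible to 0/1, with one row
#'   per component and one column per genome.
#' @param components Character vector of unique, non-empty component names.
#'   Defaults to `rownames(states)`.
#' @param genomes Character vector of unique, non-empty genome codes.
#'   Defaults to `colnames(states)`.
#' @param annotation Optional named character vector mapping components to
#'   a category label. Unnamed vectors of length `nrow(states)` are matched
#'   positionally.
#' @param provenance Free-text source note carried through serialization.
#' @return An object of class `presence_matrix` with fields `states`
#'   (integer 0/1 matrix with dimnames), `annotation` and `provenance`.
#' @examples
#' m <- presence_matrix(rbind(A = c(1, 0), B = c(1, 1)),
#'                      genomes = c("g1", "g2"))
#' m$states
#' @export
presence_matrix <- function(states, components = rownames(states),
                            genomes = colnames(states), annotation = NULL,
                            provenance = "") {
  states <- as.matrix(states)
  if (is.null(components) || is.null(genomes))
    stop("components and genomes must be supplied or present as dimnames")
  components <- as.character(components)
  genomes <- as.character(genomes)
  if (nrow(states) != length(components) || ncol(states) != length(genomes))
    stop("states shape must equal |components| x |genomes|")
  mode(states) <- "integer"
  dimnames(states) <- list(components, genomes)
  if (!is.null(annotation)) {
    annotation <- if (is.null(names(annotation)))
      stats::setNames(as.character(annotation), components)
    else annotation[components]
  }
  obj <- structure(list(states = states, annotation = annotation,
                        provenance = as.character(provenance)[1]),
                   class = "presence_matrix")
  validate_presence_matrix(obj)
}

#' Validate a presence/absence matrix
#'
#' Checks the class invariants: unique non-empty component and genome
#' names, strictly binary states, and shape consistency.
#'
#' @param m A `presence_matrix`.
#' @return `m`, invisibly unchanged, or an error describing the violation.
#' @export
validate_presence_matrix <- function(m) {
  stopifnot(inherits(m, "presence_matrix"))
  comp <- rownames(m$states)
  gen <- colnames(m$states)
  if (anyNA(comp) || any(!nzchar(comp)))
    stop("component names must be non-empty")
  if (anyNA(gen) || any(!nzchar(gen)))
    stop("genome names must be non-empty")
  if (anyDuplicated(comp))
    stop("duplicate component names: ",
         paste(unique(comp[duplicated(comp)]), collapse = ", "))
  if (anyDuplicated(gen))
    stop("duplicate genome codes: ",
         paste(unique(gen[duplicated(gen)]), collapse = ", "))
  if (length(m$states) && (anyNA(m$states) || !all(m$states %in% c(0L, 1L))))
    stop("states must be 0 or 1")
  if (!is.null(m$annotation) &&
      !identical(names(m$annotation), comp))
    stop("annotation must be named by component")
  m
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d components x %d genomes\n",
              nrow(x$states), ncol(x$states)))
  if (!is.null(x$annotation))
    cat("annotation categories:",
        paste(unique(x$annotation), collapse = ", "), "\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Components and genomes of a presence matrix
#'
#' @param m A `presence_matrix`.
#' @return Character vector of component names or genome codes, in matrix
#'   order.
#' @export
matrix_components <- function(m) rownames(m$states)

#' @rdname matrix_components
#' @export
matrix_genomes <- function(m) colnames(m$states)

#' Read a presence/absence matrix from a tab-separated table
#'
#' Expected layout: optional leading `#` comment lines (the first one, if
#' any, is taken as the provenance note); a header row whose first cell
#' labels the component column, optionally followed by a cell named
#' `annotation`, then the genome codes; one row per component with cells
#' that are either the presence mark or empty. Mark parsing is
#' case-insensitive, so a stray upper-case mark in an otherwise lower-case
#' table is read as present.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param mark Cell token denoting presence (default `"x"`).
#' @return A validated [presence_matrix()].
#' @export
read_presence_matrix <- function(path, mark = "x") {
  raw <- readLines(path, encoding = "UTF-8")
  comments <- grepl("^#", raw)
  provenance <- if (any(comments)) sub("^#\\s?", "", raw[comments][1]) else ""
  raw <- raw[!comments & nzchar(raw)]
  if (!length(raw)) stop("no header row in ", path)
  cells <- strsplit(raw, "\t", fixed = TRUE)
  header <- cells[[1]]
  has_annot <- length(header) >= 2 && identical(tolower(header[2]), "annotation")
  first_data <- if (has_annot) 3L else 2L
  genomes <- header[seq_along(header) >= first_data]
  n_gen <- length(genomes)
  body <- cells[-1]
  components <- vapply(body, `[`, "", 1L)
  annotation <- if (has_annot && length(body))
    vapply(body, `[`, "", 2L) else NULL
  states <- matrix(0L, length(components), n_gen)
  for (i in seq_along(body)) {
    row <- body[[i]][-seq_len(first_data - 1L)]
    length(row) <- n_gen        # pad truncated trailing empties
    row[is.na(row)] <- ""
    bad <- !(tolower(row) %in% c(tolower(mark), ""))
    if (any(bad))
      stop(sprintf("unknown cell token '%s' at component '%s', genome '%s'",
                   row[bad][1], components[i], genomes[which(bad)[1]]))
    states[i, ] <- as.integer(tolower(row) == tolower(mark))
  }
  presence_matrix(states, components, genomes, annotation = annotation,
                  provenance = provenance)
}

#' Write a presence/absence matrix to a tab-separated table
#'
#' Output is deterministic and byte-identical for identical input: rows
#' and columns are emitted in stored order, presence as `mark`, absence as
#' an empty cell. A non-empty provenance note is written as a leading `#`
#' comment; an annotation map is written as an extra `annotation` column.
#'
#' @param m A valid `presence_matrix`.
#' @param path Output path.
#' @param mark Presence token to emit.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(m, path, mark = "x") {
  validate_presence_matrix(m)
  con <- file(path, open = "wb")
  on.exit(close(con))
  out <- character(0)
  if (nzchar(m$provenance)) out <- paste0("# ", m$provenance)
  header <- c("component", if (!is.null(m$annotation)) "annotation",
              matrix_genomes(m))
  out <- c(out, paste(header, collapse = "\t"))
  for (i in seq_len(nrow(m$states))) {
    cells <- ifelse(m$states[i, ] == 1L, mark, "")
    row <- c(matrix_components(m)[i],
             if (!is.null(m$annotation)) unname(m$annotation[i]), cells)
    out <- c(out, paste(row, collapse = "\t"))
  }
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct a taxonomy map
#'
#' Maps genome codes to a taxonomic class and to one of the eukaryote
#' supergroups used throughout the package. The supergroup universe is
#' ordered and configurable; labels outside the universe are an error
#' rather than silently ignored.
#'
#' @param genome Character vector of unique genome codes.
#' @param class Character vector of taxonomic class labels.
#' @param supergroup Character vector of supergroup labels, each in
#'   `universe`.
#' @param species Optional character vector of species names.
#' @param universe Ordered supergroup universe. Defaults to
#'   [supergroup_universe()].
#' @return An object of class `taxonomy_map`: a data frame with columns
#'   `genome`, `class`, `supergroup`, `species` and a `universe` attribute.
#' @export
taxonomy_map <- function(genome, class, supergroup, species = NULL,
                         universe = supergroup_universe()) {
  genome <- as.character(genome)
  if (anyDuplicated(genome))
    stop("duplicate genome codes in taxonomy")
  bad <- setdiff(unique(supergroup), universe)
  if (length(bad))
    stop("supergroup labels outside the declared universe: ",
         paste(bad, collapse = ", "))
  df <- data.frame(genome = genome, class = as.character(class),
                   supergroup = as.character(supergroup),
                   species = if (is.null(species)) NA_character_
                             else as.character(species),
                   stringsAsFactors = FALSE)
  structure(df, universe = universe,
            class = c("taxonomy_map", "data.frame"))
}

#' The default eukaryote supergroup universe
#'
#' The five supergroups used for profiling and ancestral reconstruction,
#' in canonical reporting order.
#'
#' @return Character vector of length five.
#' @export
supergroup_universe <- function() {
  c("Opisthokonts", "Amoebozoa", "Plantae", "Chromalveolates", "Excavates")
}

#' Read a taxonomy map from a tab-separated table
#'
#' Expects a header row and columns `genome`, `class`, `supergroup` and
#' optionally `species`; `#` comment lines are skipped.
#'
#' @param path Path to the file.
#' @param universe Ordered supergroup universe.
#' @return A [taxonomy_map()].
#' @export
read_taxonomy_map <- function(path, universe = supergroup_universe()) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("genome", "class", "supergroup")
  if (!all(need %in% names(df)))
    stop("taxonomy file must have columns genome, class, supergroup")
  taxonomy_map(df$genome, df$class, df$supergroup,
               species = if ("species" %in% names(df)) df$species,
               universe = universe)
}

#' Look up supergroups for genomes, erroring on unmapped codes
#' @noRd
supergroup_of <- function(genomes, taxonomy) {
  idx <- match(genomes, taxonomy$genome)
  if (anyNA(idx))
    stop("genomes missing from taxonomy: ",
         paste(genomes[is.na(idx)], collapse = ", "))
  stats::setNames(taxonomy$supergroup[idx], genomes)
}
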