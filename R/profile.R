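#' @useDynLib lecatrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# the 20-letter amino-acid alphabet used throughout; 'X' is permitted in
# sequences and scores as background (0 bits)
aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @noRd
seq_to_idx <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, aa_alphabet())
  idx[is.na(idx)] <- 0L
  idx - 1L  # 0-based; -1 marks 'X'/unknown
}

#' @noRd
check_protein <- function(sequence, id = "?") {
  if (!nzchar(sequence)) stop("empty sequence for ", id)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]),
                 c(aa_alphabet(), "X"))
  if (length(bad))
    stop("invalid residues in ", id, ": ", paste(bad, collapse = ""))
  invisible(sequence)
}

#' Construct a seed alignment
#'
#' A seed alignment is the curated, aligned set of sequences from which a
#' scoring profile for one component is built.
#'
#' @param component Component name.
#' @param sequences Character vector of aligned sequences (equal length,
#'   gap character `-`), optionally named by source genome.
#' @param source_genomes Optional character vector of source genomes.
#' @return An object of class `seed_alignment`.
#' @export
seed_alignment <- function(component, sequences, source_genomes = NULL) {
  sequences <- as.character(sequences)
  if (!length(sequences)) stop("seed alignment needs at least one sequence")
  if (length(unique(nchar(sequences))) != 1L)
    stop("aligned sequences must have equal length")
  for (s in sequences) {
    bad <- setdiff(unique(strsplit(s, "")[[1]]), c(aa_alphabet(), "X", "-"))
    if (length(bad))
      stop("invalid characters in seed alignment: ", paste(bad, collapse = ""))
  }
  if (is.null(source_genomes))
    source_genomes <- if (!is.null(names(sequences))) names(sequences)
                      else rep(NA_character_, length(sequences))
  structure(list(component = component, sequences = unname(sequences),
                 source_genomes = source_genomes),
            class = "seed_alignment")
}

#' Read a seed alignment from an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @param component Component name; defaults to the file name without
#'   extension.
#' @return A [seed_alignment()].
#' @export
read_seed_alignment <- function(path, component = NULL) {
  if (is.null(component))
    component <- sub("\\.[^.]*$", "", basename(path))
  aln <- Biostrings::readAAStringSet(path)
  seed_alignment(component, as.character(aln),
                 source_genomes = names(aln))
}

#' Build a position-specific scoring profile from a seed alignment
#'
#' Alignment columns with more than 50% gaps are treated as insert states
#' and excluded; the remaining match columns get per-residue log-odds
#' scores (bits) from pseudocounted column frequencies against the
#' background. With `pseudocount_weight > 0` every score is finite.
#'
#' @param seed A [seed_alignment()].
#' @param mode `"local"` (best-scoring segment) or `"global"` (full
#'   profile against its best sequence segment).
#' @param pseudocount_weight Non-negative total weight of the background
#'   pseudocount added to each column (default 1).
#' @param background Background residue frequencies (length 20, summing to
#'   1); default uniform.
#' @param gap_open,gap_extend Affine gap penalties in bits, applied per
#'   column.
#' @return An object of class `scoring_profile` with fields `component`,
#'   `scores` (match columns x 20 residues, bits), `gap_open`,
#'   `gap_extend`, `background`, `mode`, `consensus` and `max_score`.
#' @examples
#' p <- build_profile(seed_alignment("toy", rep("MKLVNN", 5)))
#' p$consensus
#' @export
build_profile <- function(seed, mode = c("local", "global"),
                          pseudocount_weight = 1,
                          background = rep(1 / 20, 20),
                          gap_open = 4, gap_extend = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(seed, "seed_alignment"), pseudocount_weight >= 0)
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  aa <- aa_alphabet()
  mat <- do.call(rbind, strsplit(seed$sequences, ""))
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac <= 0.5)
  if (!length(match_cols)) stop("degenerate profile: no match columns")
  scores <- matrix(0, length(match_cols), 20,
                   dimnames = list(NULL, aa))
  for (k in seq_along(match_cols)) {
    col <- mat[, match_cols[k]]
    col <- col[col %in% aa]
    counts <- table(factor(col, levels = aa))
    freq <- (as.numeric(counts) + pseudocount_weight * background) /
      (length(col) + pseudocount_weight)
    scores[k, ] <- log2(freq / background)
  }
  consensus <- paste(aa[apply(scores, 1, which.max)], collapse = "")
  structure(list(component = seed$component, scores = scores,
                 gap_open = rep(gap_open, length(match_cols)),
                 gap_extend = rep(gap_extend, length(match_cols)),
                 background = background, mode = mode,
                 match_cols = match_cols, consensus = consensus,
                 max_score = sum(apply(scores, 1, max))),
            class = "scoring_profile")
}

#' @export
print.scoring_profile <- function(x, ...) {
  cat(sprintf("scoring_profile '%s': %d match columns, mode %s, max %.1f bits\n",
              x$component, nrow(x$scores), x$mode, x$max_score))
  invisible(x)
}

#' Score a protein against a scoring profile
#'
#' Runs the affine-gap dynamic programme in the profile's mode and
#' returns the best-scoring hit. Local mode reports the best-scoring
#' segment; global mode aligns the full profile against its best sequence
#' segment. Ties are broken by leftmost start, then shortest interval, so
#' the result is deterministic.
#'
#' @param profile A [scoring_profile()].
#' @param sequence Protein sequence (alphabet plus `X`, which scores 0).
#' @param id Protein identifier carried into the hit.
#' @return An object of class `hit_record`: `protein_id`, `component`,
#'   `score` (bits), `start`/`end` (0-based half-open interval on the
#'   protein) and `match_pos` (0-based sequence position per match
#'   column, `NA` for deleted columns).
#' @export
score_sequence <- function(profile, sequence, id = "query") {
  check_protein(sequence, id)
  res <- profile_align_cpp(profile$scores, profile$gap_open,
                           profile$gap_extend, seq_to_idx(sequence),
                           identical(profile$mode, "local"))
  structure(list(protein_id = id, component = profile$component,
                 score = res$score, start = res$start, end = res$end,
                 match_pos = res$match_pos),
            class = "hit_record")
}

#' @export
print.hit_record <- function(x, ...) {
  cat(sprintf("hit: %s vs %s, %.2f bits, interval [%d, %d)\n",
              x$protein_id, x$component, x$score, x$start, x$end))
  invisible(x)
}

#' Construct a set of protein records
#'
#' @param id Unique protein identifiers.
#' @param genome Genome code per protein.
#' @param sequence Amino-acid sequences (alphabet plus `X`).
#' @param component Optional component label per protein (used for
#'   labelled reference sets in reciprocal validation).
#' @return A data frame of class `protein_records`.
#' @export
protein_records <- function(id, genome, sequence, component = NULL) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate protein ids")
  sequence <- as.character(sequence)
  mapply(check_protein, sequence, id)
  structure(data.frame(id = id, genome = as.character(genome),
                       sequence = sequence,
                       component = if (is.null(component)) NA_character_
                                   else as.character(component),
                       stringsAsFactors = FALSE),
            class = c("protein_records", "data.frame"))
}

#' Read a proteome from a FASTA file
#'
#' @param path FASTA path.
#' @param genome Genome code assigned to all records.
#' @return A [protein_records()] set.
#' @export
read_proteome <- function(path, genome = "unknown") {
  seqs <- Biostrings::readAAStringSet(path)
  protein_records(names(seqs), genome, as.character(seqs))
}

#' Write protein records to a FASTA file
#'
#' @param records A [protein_records()] set.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(records, path) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
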