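#' Supergroup profile of a presence matrix
#'
#' Maps each component to the set of supergroups in which it is present in
#' at least one genome.
#'
#' @param m A [presence_matrix()].
#' @param taxonomy A [taxonomy_map()] covering every genome of `m`.
#' @return A named list (class `supergroup_profile`), one character vector
#'   of supergroup labels per component, ordered as in the taxonomy
#'   universe. The universe is attached as attribute `"universe"`.
#' @examples
#' m <- load_fixture("nup_table2")
#' presence_by_supergroup(m, fixture_taxonomy(m))[["Sec13"]]
#' @export
presence_by_supergroup <- function(m, taxonomy) {
  validate_presence_matrix(m)
  sg <- supergroup_of(matrix_genomes(m), taxonomy)
  universe <- attr(taxonomy, "universe")
  prof <- lapply(seq_len(nrow(m$states)), function(i) {
    hit <- unique(sg[m$states[i, ] == 1L])
    universe[universe %in% hit]
  })
  names(prof) <- matrix_components(m)
  structure(prof, universe = universe, class = "supergroup_profile")
}

#' @export
print.supergroup_profile <- function(x, ...) {
  cat(sprintf("supergroup_profile: %d components over {%s}\n", length(x),
              paste(attr(x, "universe"), collapse = ", ")))
  invisible(x)
}

#' Per-supergroup component counts
#'
#' For each supergroup, the number of components present in at least one
#' of its genomes (the "components in supergroup" bottom row of a survey
#' table).
#'
#' @inheritParams presence_by_supergroup
#' @return Named integer vector over the taxonomy universe.
#' @export
supergroup_counts <- function(m, taxonomy) {
  prof <- presence_by_supergroup(m, taxonomy)
  universe <- attr(prof, "universe")
  counts <- vapply(universe, function(g)
    sum(vapply(prof, function(p) g %in% p, logical(1))), integer(1))
  stats::setNames(counts, universe)
}

#' Collapse a genome-level matrix to supergroup leaves
#'
#' Supergroup state is the OR over member genomes; the result is a
#' [presence_matrix()] whose genomes are the supergroup labels, in
#' universe order, restricted to supergroups with at least one genome in
#' `m`.
#'
#' @inheritParams presence_by_supergroup
#' @return A [presence_matrix()] over supergroup columns.
#' @export
collapse_to_supergroups <- function(m, taxonomy) {
  validate_presence_matrix(m)
  sg <- supergroup_of(matrix_genomes(m), taxonomy)
  universe <- attr(taxonomy, "universe")
  present_groups <- universe[universe %in% unique(sg)]
  states <- vapply(present_groups, function(g) {
    cols <- which(sg == g)
    as.integer(rowSums(m$states[, cols, drop = FALSE]) > 0)
  }, integer(nrow(m$states)))
  if (nrow(m$states) == 1L) states <- matrix(states, nrow = 1L)
  presence_matrix(states, matrix_components(m), present_groups,
                  annotation = m$annotation,
                  provenance = if (nzchar(m$provenance))
                    paste(m$provenance, "(collapsed to supergroups)")
                  else "")
}

#' Components present in every supergroup
#'
#' The universal set: components found in at least one genome from each of
#' the supergroups in the taxonomy universe.
#'
#' @inheritParams presence_by_supergroup
#' @return Character vector of component names, in matrix order.
#' @export
universal_components <- function(m, taxonomy) {
  prof <- presence_by_supergroup(m, taxonomy)
  universe <- attr(prof, "universe")
  names(prof)[vapply(prof, function(p) all(universe %in% p), logical(1))]
}
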