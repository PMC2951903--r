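#' Association between component presence and mitosis phenotype
#'
#' Builds the 2x2 contingency table of component presence/absence against
#' a binary phenotype (genomes labelled `unknown` are dropped), flags
#' perfect association (both off-diagonal cells zero) and attaches a
#' two-sided exact p-value from the conditional (hypergeometric) null
#' over all margin-preserving tables. The exact test is an added
#' operationalization: the underlying surveys report the pattern, not a
#' statistic.
#'
#' @param m A [presence_matrix()] over the phenotyped genomes.
#' @param phenotypes A [phenotype_map()].
#' @param component Component name to test.
#' @return A list of class `mitosis_association` with `table` (2x2 counts,
#'   phenotype levels as columns), `perfect` (logical) and `p_value`.
#' @examples
#' m <- load_fixture("fungi_table4")
#' mitosis_association(m, load_fixture("mitosis_phenotypes"), "Pom34")
#' @export
mitosis_association <- function(m, phenotypes, component) {
  validate_presence_matrix(m)
  if (!(component %in% matrix_components(m)))
    stop("unknown component: ", component)
  ph <- stats::setNames(phenotypes$phenotype, phenotypes$genome)
  gen <- matrix_genomes(m)
  ph <- ph[gen]
  if (anyNA(ph)) stop("genomes missing from phenotype map: ",
                      paste(gen[is.na(ph)], collapse = ", "))
  keep <- ph != "unknown"
  ph <- factor(ph[keep], levels = c("closed", "open"))
  if (any(table(ph) == 0))
    stop("degenerate input: a phenotype class is empty after dropping unknowns")
  present <- factor(ifelse(m$states[component, gen[keep]] == 1L,
                           "present", "absent"),
                    levels = c("present", "absent"))
  tab <- table(present, ph)
  perfect <- (tab["present", "open"] == 0 && tab["absent", "closed"] == 0) ||
             (tab["present", "closed"] == 0 && tab["absent", "open"] == 0)
  structure(list(component = component, table = tab, perfect = perfect,
                 p_value = exact_table_pvalue(tab)),
            class = "mitosis_association")
}

#' Two-sided exact p-value for a 2x2 table
#'
#' Conditional on both margins, the cell count follows a hypergeometric
#' distribution; the two-sided p-value sums the probabilities of all
#' margin-preserving tables no more probable than the observed one (the
#' usual exact-test convention).
#'
#' @param tab A 2x2 matrix of counts.
#' @return Numeric p-value in `(0, 1]`.
#' @export
exact_table_pvalue <- function(tab) {
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  sum(probs[probs <= stats::dhyper(a, m1, m2, k) * (1 + 1e-7)])
}

#' @export
print.mitosis_association <- function(x, ...) {
  cat(sprintf("component %s vs mitosis phenotype%s\n", x$component,
              if (x$perfect) " (perfect association)" else ""))
  print(x$table)
  cat(sprintf("two-sided exact p-value (added statistic): %.4g\n", x$p_value))
  invisible(x)
}

#' Whole-supergroup absences of complex components
#'
#' Lists the components (or paralog groups, collapsed by OR before
#' testing) that are entirely absent from at least one supergroup, with
#' the absent supergroups. Paralog groups are disjoint component sets
#' treated as a single evolutionary unit, e.g. the vertebrate/fungal
#' apl1 arising by duplication from the broadly distributed apl2.
#'
#' @param m A [presence_matrix()].
#' @param taxonomy The matching [taxonomy_map()].
#' @param paralog_groups Named list of disjoint character vectors of
#'   component names; each group is collapsed by OR under its name.
#' @return A data frame of class `difference_report` with columns
#'   `component` (or group name) and `absent_from` (comma-separated
#'   supergroups), one row per flagged unit.
#' @examples
#' m <- load_fixture("coatomer_table5")
#' coatomer_supergroup_differences(m, fixture_taxonomy(m),
#'                                 paralog_groups = list(apl = c("apl1", "apl2")))
#' @export
coatomer_supergroup_differences <- function(m, taxonomy,
                                            paralog_groups = list()) {
  validate_presence_matrix(m)
  comps <- matrix_components(m)
  grouped <- unlist(paralog_groups)
  if (length(grouped)) {
    unknown <- setdiff(grouped, comps)
    if (length(unknown))
      stop("paralog group references unknown component: ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(grouped)) stop("paralog groups must be disjoint")
  }
  states <- m$states
  for (g in names(paralog_groups)) {
    members <- paralog_groups[[g]]
    merged <- as.integer(colSums(states[members, , drop = FALSE]) > 0)
    states <- states[setdiff(rownames(states), members), , drop = FALSE]
    states <- rbind(states, matrix(merged, 1,
                                   dimnames = list(g, colnames(states))))
  }
  mm <- presence_matrix(states, provenance = m$provenance)
  prof <- presence_by_supergroup(mm, taxonomy)
  universe <- attr(prof, "universe")
  rows <- lapply(names(prof), function(cn) {
    absent <- setdiff(universe, prof[[cn]])
    if (length(absent) && length(prof[[cn]]))
      data.frame(component = cn,
                 absent_from = paste(absent, collapse = ","),
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(component = character(0), absent_from = character(0))
  structure(out, class = c("difference_report", "data.frame"))
}

#' Compare per-supergroup component counts across studies
#'
#' Takes a named collection of supergroup profiles (see
#' [presence_by_supergroup()]) over the same component universe and
#' tabulates, per study, how many components were recovered in each
#' supergroup, alongside the per-component presence grid.
#'
#' @param profiles Named list of `supergroup_profile` objects.
#' @return A list of class `study_comparison` with `counts` (supergroups
#'   x studies integer matrix) and `grid` (a data frame with one row per
#'   component and one logical column per study/supergroup pair).
#' @export
study_comparison <- function(profiles) {
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  universe <- attr(profiles[[1]], "universe")
  comps <- names(profiles[[1]])
  for (p in profiles[-1])
    if (!setequal(names(p), comps))
      warning("component universes differ: ",
              paste(union(setdiff(names(p), comps),
                          setdiff(comps, names(p))), collapse = ", "))
  counts <- vapply(profiles, function(p)
    vapply(universe, function(g)
      sum(vapply(p, function(x) g %in% x, logical(1))), integer(1)),
    integer(length(universe)))
  if (length(universe) == 1L) counts <- matrix(counts, nrow = 1L)
  dimnames(counts) <- list(universe, names(profiles))
  grid <- do.call(cbind, lapply(names(profiles), function(st) {
    g <- vapply(universe, function(sg)
      vapply(comps, function(cn) sg %in% profiles[[st]][[cn]], logical(1)),
      logical(length(comps)))
    if (length(comps) == 1L) g <- matrix(g, nrow = 1L)
    colnames(g) <- paste(st, universe, sep = ".")
    g
  }))
  grid <- data.frame(component = comps, grid, check.names = FALSE,
                     stringsAsFactors = FALSE)
  structure(list(counts = counts, grid = grid), class = "study_comparison")
}

#' @export
print.study_comparison <- function(x, ...) {
  cat("components recovered per supergroup and study:\n")
  print(x$counts)
  invisible(x)
}

#' Render a human-readable summary of a survey and its reconstruction
#'
#' Produces a deterministic plain-text report in the style of a
#' distribution-summary figure: components grouped by their annotation
#' category (e.g. NPC subcomplex), the supergroups each is found in,
#' universal components marked, and — when a reconstruction is supplied —
#' the inferred ancestral complement.
#'
#' @param m A [presence_matrix()].
#' @param taxonomy The matching [taxonomy_map()].
#' @param leca Optional character vector of ancestral-complement
#'   components (from [leca_complement()]).
#' @return A list of class `summary_report` with `text` (character lines)
#'   and `table` (a data frame: component, annotation, supergroups,
#'   universal, in_leca).
#' @export
render_summary <- function(m, taxonomy, leca = NULL) {
  validate_presence_matrix(m)
  prof <- presence_by_supergroup(m, taxonomy)
  universe <- attr(prof, "universe")
  comps <- matrix_components(m)
  universal <- universal_components(m, taxonomy)
  tab <- data.frame(
    component = comps,
    annotation = if (is.null(m$annotation))
      rep(NA_character_, length(comps)) else unname(m$annotation[comps]),
    supergroups = vapply(comps, function(cn)
      paste(prof[[cn]], collapse = ","), ""),
    universal = comps %in% universal,
    in_leca = if (is.null(leca)) rep(NA, length(comps))
              else comps %in% leca,
    stringsAsFactors = FALSE, row.names = NULL)
  lines <- c(sprintf("survey: %d components x %d genomes over {%s}",
                     nrow(m$states), ncol(m$states),
                     paste(universe, collapse = ", ")),
             sprintf("universal components (all supergroups): %d",
                     length(universal)))
  if (!is.null(leca))
    lines <- c(lines, sprintf("ancestral complement: %d components",
                              length(leca)))
  cats <- if (is.null(m$annotation)) "all components"
          else unique(unname(m$annotation[comps]))
  for (cat_i in cats) {
    members <- if (is.null(m$annotation)) comps
               else comps[unname(m$annotation[comps]) == cat_i]
    lines <- c(lines, paste0("[", cat_i, "]"))
    for (cn in members)
      lines <- c(lines, sprintf("  %s%s: %s", cn,
                                if (cn %in% universal) "*" else "",
                                tab$supergroups[tab$component == cn]))
  }
  structure(list(text = lines, table = tab), class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
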