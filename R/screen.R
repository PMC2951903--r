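#' Screen a proteome with a set of scoring profiles
#'
#' Scores every protein against every profile and keeps, per component,
#' the hits at or above the threshold, ranked by score (descending) with
#' ties broken by protein id. A protein may hit several profiles;
#' disambiguation is the job of [reciprocal_validate()].
#'
#' @param profiles A list of [scoring_profile()] objects (or a single
#'   one).
#' @param proteome A [protein_records()] set.
#' @param threshold Either a numeric score in bits, or a list
#'   `list(quantile = q, decoys = scores)` resolving to the `q`-th
#'   quantile of a supplied decoy score set.
#' @return A named list (by component) of data frames with columns
#'   `protein_id`, `genome`, `component`, `score`, `start`, `end` and a
#'   list column `match_pos`.
#' @export
screen_proteome <- function(profiles, proteome, threshold) {
  if (inherits(profiles, "scoring_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("at least one profile is required")
  thr <- resolve_threshold(threshold)
  out <- lapply(profiles, function(p) {
    hits <- lapply(seq_len(nrow(proteome)), function(i) {
      h <- score_sequence(p, proteome$sequence[i], proteome$id[i])
      if (h$score >= thr)
        data.frame(protein_id = h$protein_id, genome = proteome$genome[i],
                   component = p$component, score = h$score,
                   start = h$start, end = h$end, stringsAsFactors = FALSE,
                   match_pos = I(list(h$match_pos)))
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits))
      hits <- data.frame(protein_id = character(0), genome = character(0),
                         component = character(0), score = numeric(0),
                         start = integer(0), end = integer(0),
                         match_pos = I(list()))
    hits[order(-hits$score, hits$protein_id), , drop = FALSE]
  })
  names(out) <- vapply(profiles, `[[`, "", "component")
  out
}

#' Resolve a screening threshold specification
#'
#' @param threshold Numeric bits, or `list(quantile = q, decoys = scores)`.
#' @return Numeric threshold in bits.
#' @export
resolve_threshold <- function(threshold) {
  if (is.numeric(threshold) && length(threshold) == 1L)
    return(as.numeric(threshold))
  if (is.list(threshold) && !is.null(threshold$quantile) &&
      !is.null(threshold$decoys) && length(threshold$decoys))
    return(unname(stats::quantile(threshold$decoys, threshold$quantile)))
  stop("unresolvable threshold specification")
}

#' Repeat windows of a protein sequence
#'
#' Operational definitions of the two low-complexity repeat classes used
#' in vetting:
#'
#' * `FG`: every occurrence of the FG dipeptide (which covers the GLFG and
#'   FxFG contexts) expanded by two residues on each side.
#' * `WD`: every match of the WD-repeat consensus anchor
#'   `[LIV]x(6,12)WD`, taken as a 40-residue window ending at the
#'   aspartate.
#'
#' @param sequence Protein sequence.
#' @param repeat_class `"FG"` or `"WD"`.
#' @return Sorted integer vector of 1-based positions inside repeat
#'   windows.
#' @export
repeat_windows <- function(sequence, repeat_class = c("FG", "WD")) {
  repeat_class <- match.arg(repeat_class)
  n <- nchar(sequence)
  pos <- integer(0)
  if (repeat_class == "FG") {
    m <- gregexpr("FG", sequence, fixed = TRUE)[[1]]
    if (m[1] != -1L)
      for (s in as.integer(m))
        pos <- c(pos, max(1L, s - 2L):min(n, s + 3L))
  } else {
    m <- gregexpr("(?=([LIV].{6,12}WD))", sequence, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      lens <- attr(m, "capture.length")[, 1]
      for (k in seq_along(m)) {
        end <- as.integer(m[k]) + lens[k] - 1L
        pos <- c(pos, max(1L, end - 39L):end)
      }
    }
  }
  sort(unique(pos))
}

#' Fraction of matched positions inside repeat windows
#'
#' @param hit A [score_sequence()] hit record, or any list with a
#'   `match_pos` field of 0-based sequence positions.
#' @param sequence The protein sequence the hit refers to.
#' @param repeat_class `"FG"` or `"WD"`.
#' @return Fraction in `[0, 1]`; 0 when the hit matches no position.
#' @export
detect_repeat_coverage <- function(hit, sequence, repeat_class = c("FG", "WD")) {
  repeat_class <- match.arg(repeat_class)
  mp <- hit$match_pos[!is.na(hit$match_pos)]
  if (any(mp < 0) || any(mp >= nchar(sequence)))
    stop("hit interval outside sequence bounds")
  if (!length(mp)) return(0)
  win <- repeat_windows(sequence, repeat_class)
  mean((mp + 1L) %in% win)
}

#' Apply vetting rules to screen hits
#'
#' Implements the annotation rules of the screen: a hit whose matched
#' positions fall essentially entirely inside FG- or WD-repeat windows is
#' rejected (`repeat_only_similarity`) unless a required motif for the
#' component occurs outside those windows; a hit missing a configured
#' required motif (e.g. the SIEGR motif of Rae1) is rejected
#' (`motif_absent`); all other hits pass on to reciprocal validation. A
#' warn tier flags hits whose repeat coverage exceeds `warn_cutoff`
#' without reaching the rejection cutoff.
#'
#' @param hits A flat data frame of hits, or the per-component list from
#'   [screen_proteome()].
#' @param sequences Named character vector (or [protein_records()])
#'   mapping protein ids to sequences.
#' @param repeat_fraction_cutoff Coverage at or above which repeat-only
#'   similarity is rejected (default 0.9).
#' @param warn_cutoff Coverage at or above which a warning flag is set
#'   (default 0.75).
#' @param required_motifs Named list mapping component names to a fixed
#'   motif string; components without an entry have no motif rule.
#' @return A data frame of class `screen_decisions` with columns
#'   `protein_id`, `genome`, `component`, `score`, `start`, `end`,
#'   `status` (`accepted`/`rejected`), `reason` (`none`,
#'   `repeat_only_similarity`, `motif_absent`), `repeat_class` and
#'   `repeat_warn`.
#' @export
apply_vetting <- function(hits, sequences, repeat_fraction_cutoff = 0.9,
                          warn_cutoff = 0.75, required_motifs = list()) {
  stopifnot(repeat_fraction_cutoff >= 0, repeat_fraction_cutoff <= 1)
  if (inherits(sequences, "protein_records"))
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  if (is.list(hits) && !is.data.frame(hits))
    hits <- do.call(rbind, hits)
  decide <- function(i) {
    seqc <- sequences[[hits$protein_id[i]]]
    if (is.null(seqc)) stop("no sequence for ", hits$protein_id[i])
    hit <- list(match_pos = hits$match_pos[[i]])
    cov <- c(FG = detect_repeat_coverage(hit, seqc, "FG"),
             WD = detect_repeat_coverage(hit, seqc, "WD"))
    cls <- names(cov)[which.max(cov)]
    motif <- required_motifs[[hits$component[i]]]
    if (max(cov) >= repeat_fraction_cutoff) {
      motif_outside <- FALSE
      if (!is.null(motif)) {
        occ <- gregexpr(motif, seqc, fixed = TRUE)[[1]]
        if (occ[1] != -1L) {
          win <- repeat_windows(seqc, cls)
          # an occurrence counts as outside unless fully inside the windows
          motif_outside <- any(vapply(as.integer(occ), function(s)
            !all(s:(s + nchar(motif) - 1L) %in% win), logical(1)))
        }
      }
      if (!motif_outside)
        return(list(status = "rejected", reason = "repeat_only_similarity",
                    repeat_class = cls, warn = TRUE))
    }
    if (!is.null(motif) && gregexpr(motif, seqc, fixed = TRUE)[[1]][1] == -1L)
      return(list(status = "rejected", reason = "motif_absent",
                  repeat_class = NA_character_, warn = FALSE))
    list(status = "accepted", reason = "none", repeat_class = NA_character_,
         warn = max(cov) >= warn_cutoff)
  }
  dec <- lapply(seq_len(nrow(hits)), decide)
  out <- data.frame(protein_id = hits$protein_id, genome = hits$genome,
                    component = hits$component, score = hits$score,
                    start = hits$start, end = hits$end,
                    status = vapply(dec, `[[`, "", "status"),
                    reason = vapply(dec, `[[`, "", "reason"),
                    repeat_class = vapply(dec, `[[`, "", "repeat_class"),
                    repeat_warn = vapply(dec, `[[`, TRUE, "warn"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("screen_decisions", "data.frame"))
}

#' Reciprocal best-hit validation of a candidate
#'
#' The candidate is aligned (substitution-matrix local alignment,
#' BLOSUM62) against a labelled reference proteome; it passes when its
#' best-scoring reference sequence carries the same component label that
#' recruited it. Score ties are broken by reference id in lexicographic
#' order, making the verdict deterministic.
#'
#' @param sequence Candidate protein sequence.
#' @param component Component label the candidate was recruited to.
#' @param reference A [protein_records()] set with non-`NA` `component`
#'   labels.
#' @return A list with `pass` (logical), `best_id`, `best_component` and
#'   `best_score`.
#' @export
reciprocal_validate <- function(sequence, component, reference) {
  if (!nrow(reference)) stop("reference proteome is empty")
  check_protein(sequence, "candidate")
  ord <- order(reference$id)
  reference <- reference[ord, , drop = FALSE]
  scores <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(reference$sequence),
    subject = Biostrings::AAString(sequence),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 4, scoreOnly = TRUE)
  best <- which.max(scores)  # first maximum = lexicographically smallest id
  list(pass = identical(reference$component[best], component),
       best_id = reference$id[best],
       best_component = reference$component[best],
       best_score = scores[best])
}

#' Permissive rescue search for a missing component
#'
#' When the primary screen finds no accepted homolog of a component in a
#' genome, sequences of that component from related genomes are used to
#' nominate candidates by substitution-matrix pairwise alignment; the
#' nominees are then re-scored with the component's profile at a lower
#' (permissive) threshold. Recovered hits are expected to re-enter
#' [apply_vetting()] and [reciprocal_validate()]. When the permissive
#' threshold equals the primary one the rescue output is a subset of the
#' primary screen output.
#'
#' @param profile The component's [scoring_profile()].
#' @param donors Character vector of donor sequences from related
#'   genomes.
#' @param proteome Target [protein_records()] set.
#' @param permissive_threshold Profile score threshold in bits (lower
#'   than the primary threshold).
#' @param donor_min_score Minimum BLOSUM62 local-alignment score against
#'   any donor for a protein to be nominated (default 40).
#' @return A hit data frame as in [screen_proteome()] (one component).
#' @export
rescue_search <- function(profile, donors, proteome, permissive_threshold,
                          donor_min_score = 40) {
  if (!length(donors)) stop("rescue search requires donor sequences")
  if (!nrow(proteome))
    return(screen_proteome(profile, proteome, permissive_threshold)[[1]])
  nominate <- vapply(proteome$sequence, function(s) {
    max(Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(donors),
      subject = Biostrings::AAString(s),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 4, scoreOnly = TRUE))
  }, numeric(1), USE.NAMES = FALSE)
  nominees <- proteome[nominate >= donor_min_score, , drop = FALSE]
  screen_proteome(profile, nominees, permissive_threshold)[[1]]
}

#' Concordance of screen calls with an external control set
#'
#' Compares screen outcomes with an externally established inventory of
#' complex components for a control genome. With `screen_status = NULL`
#' the statuses recorded in the control table itself are tallied;
#' otherwise a data frame of per-protein outcomes (columns `protein_id`,
#' `status`) replaces them.
#'
#' @param control A [control_reference()] table.
#' @param screen_status Optional data frame with `protein_id` and
#'   `status` columns overriding the recorded outcomes.
#' @param component_universe Optional character vector; assigned
#'   components outside it trigger a reconciliation warning (not an
#'   error).
#' @return A list of class `concordance_report`: counts
#'   (`n_orthology_established`, `n_recovered`, `n_extra_calls`,
#'   `n_excluded`, `n_excluded_fg`, `n_not_detected`, `n_unassigned`,
#'   `n_unassigned_fg`) and a per-record `reconciliation` data frame.
#' @examples
#' concordance_report(load_fixture("tbrucei_table1"))
#' @export
concordance_report <- function(control, screen_status = NULL,
                               component_universe = NULL) {
  stopifnot(inherits(control, "control_reference"))
  status <- control$status
  if (!is.null(screen_status)) {
    idx <- match(control$protein_id, screen_status$protein_id)
    status <- ifelse(is.na(idx), "not_detected", screen_status$status[idx])
  }
  if (!is.null(component_universe)) {
    out <- setdiff(stats::na.omit(control$component), component_universe)
    if (length(out))
      warning("assigned components outside the matrix universe: ",
              paste(out, collapse = ", "))
  }
  unassigned <- is.na(control$component)
  rec <- data.frame(protein_id = control$protein_id,
                    component = control$component,
                    orthology_established = control$orthology_established,
                    status = status, fg_repeats = control$fg_repeats,
                    stringsAsFactors = FALSE)
  structure(list(
    n_orthology_established = sum(control$orthology_established),
    n_recovered = sum(control$orthology_established & status == "identified"),
    n_extra_calls = sum(!control$orthology_established &
                          status == "identified"),
    n_excluded = sum(status == "excluded"),
    n_excluded_fg = sum(status == "excluded" & control$fg_repeats),
    n_not_detected = sum(status == "not_detected"),
    n_unassigned = sum(unassigned),
    n_unassigned_fg = sum(unassigned & control$fg_repeats),
    reconciliation = rec), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("orthology-established components recovered: %d/%d\n",
              x$n_recovered, x$n_orthology_established))
  cat(sprintf("extra screen calls: %d\n", x$n_extra_calls))
  cat(sprintf("control records without component assignment: %d (%d FG-flagged)\n",
              x$n_unassigned, x$n_unassigned_fg))
  cat(sprintf("excluded after hit: %d (%d FG); not detected: %d\n",
              x$n_excluded, x$n_excluded_fg, x$n_not_detected))
  invisible(x)
}

#' Write screen decisions to a tab-separated table
#'
#' @param decisions A [apply_vetting()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_decisions <- function(decisions, path) {
  utils::write.table(as.data.frame(decisions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
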