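#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generator. Every
#' randomized operation derives its own substream from the master seed and
#' a fixed label, so e.g. adding decoy classes does not perturb the
#' simulated tree.
#'
#' @param seed Master integer seed.
#' @param n_leaves Number of tree leaves (genomes).
#' @param n_components Number of binary characters (components) to
#'   evolve.
#' @param p_loss Per-branch loss probability below the gain edge.
#' @param gain `"root"` (all components gained on the root stem) or
#'   `"uniform"` (gain edge uniform over the root stem and all tree
#'   edges).
#' @param q Detection false-negative rate (present observed as absent).
#' @param r Detection false-positive rate (absent observed as present).
#' @param seq_length Planted-homolog consensus length (residues).
#' @param substitution Fraction of planted-homolog positions substituted.
#' @param indel_rate Per-position indel initiation rate in planted
#'   homologs; indel lengths are geometric with mean 2.
#' @param n_random,n_fg,n_wd Decoy counts per class per proteome.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_leaves = 16L, n_components = 100L,
                              p_loss = 0.1, gain = c("root", "uniform"),
                              q = 0, r = 0, seq_length = 240L,
                              substitution = 0.3, indel_rate = 0.02,
                              n_random = 20L, n_fg = 5L, n_wd = 5L) {
  gain <- match.arg(gain)
  probs <- c(p_loss = p_loss, q = q, r = r, substitution = substitution,
             indel_rate = indel_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  stopifnot(n_leaves >= 2, n_components >= 1, seq_length >= 10)
  structure(list(seed = as.integer(seed), n_leaves = as.integer(n_leaves),
                 n_components = as.integer(n_components), p_loss = p_loss,
                 gain = gain, q = q, r = r,
                 seq_length = as.integer(seq_length),
                 substitution = substitution, indel_rate = indel_rate,
                 n_random = as.integer(n_random), n_fg = as.integer(n_fg),
                 n_wd = as.integer(n_wd)),
            class = "simulation_config")
}

#' @noRd
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 7919)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

#' @noRd
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, label))
  expr
}

#' Simulate a random rooted binary tree
#'
#' Leaves are labelled `t1..tn`; the topology is drawn by random
#' sequential attachment and is a pure function of `(n_leaves, seed)`.
#'
#' @param n_leaves Number of leaves (at least 2).
#' @param seed Integer seed.
#' @return A rooted binary `ape::phylo` without branch lengths.
#' @export
simulate_tree <- function(n_leaves, seed = 1L) {
  if (n_leaves < 2) stop("a tree needs at least 2 leaves")
  with_substream(seed, "tree", {
    tree <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
    tree$tip.label <- paste0("t", seq_len(n_leaves))
    tree
  })
}

#' Evolve binary characters under a single-gain/multiple-loss model
#'
#' Each component is gained exactly once (on the root stem or on a
#' uniformly drawn edge, per the configuration); below the gain every
#' branch loses the component independently with probability `p_loss`,
#' and loss is absorbing. Records, per component, the gain edge (labelled
#' by its child clade, `"root"` for the stem), the realized first-loss
#' edges, and the true tip states.
#'
#' @param topology A rooted `ape::phylo`.
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_truth` with `tip_states`
#'   (components x leaves 0/1 matrix), `gain_edges`, `loss_edges` (list)
#'   and `topology`.
#' @export
simulate_dollo_evolution <- function(topology, config) {
  stopifnot(inherits(config, "simulation_config"))
  n_tip <- ape::Ntip(topology)
  kids <- tree_children(topology)
  root <- n_tip + 1L
  comp_names <- sprintf("c%03d", seq_len(config$n_components))
  with_substream(config$seed, "dollo", {
    gains <- if (config$gain == "root") rep(0L, config$n_components)
             else sample(0:nrow(topology$edge), config$n_components,
                         replace = TRUE)  # 0 = root stem
    res <- lapply(seq_len(config$n_components), function(i) {
      gain_node <- if (gains[i] == 0L) root else topology$edge[gains[i], 2]
      state <- integer(n_tip + topology$Nnode)
      losses <- character(0)
      state[gain_node] <- 1L
      if (gain_node > n_tip) {
        for (nd in tree_preorder(topology)) {
          if (nd <= n_tip || state[nd] == 0L) next
          if (!is_descendant(topology, nd, gain_node)) next
          for (ch in kids[[nd]]) {
            if (stats::runif(1) < config$p_loss)
              losses <- c(losses, clade_label(topology, ch))
            else state[ch] <- 1L
          }
        }
      }
      list(tips = state[seq_len(n_tip)],
           gain = if (gains[i] == 0L) "root" else clade_label(topology, gain_node),
           losses = sort(losses))
    })
    tips <- do.call(rbind, lapply(res, `[[`, "tips"))
    dimnames(tips) <- list(comp_names, topology$tip.label)
    structure(list(tip_states = tips,
                   gain_edges = stats::setNames(
                     vapply(res, `[[`, "", "gain"), comp_names),
                   loss_edges = stats::setNames(
                     lapply(res, `[[`, "losses"), comp_names),
                   topology = topology),
              class = "synthetic_truth")
  })
}

#' @noRd
is_descendant <- function(tree, node, ancestor) {
  if (node == ancestor) return(TRUE)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  parent <- function(nd) tree$edge[tree$edge[, 2] == nd, 1]
  while (node != root) {
    node <- parent(node)
    if (node == ancestor) return(TRUE)
  }
  FALSE
}

#' Apply detection noise to true tip states
#'
#' Each true presence flips to absence with probability `q` and each true
#' absence to presence with probability `r`. The noise is coupled across
#' rates: one uniform draw per cell (a pure function of the seed) is
#' compared against the rate, so raising `q` flips a superset of the
#' cells flipped at any lower `q`. This makes detection-noise sweeps
#' monotone by construction.
#'
#' @param tip_states 0/1 matrix of true states.
#' @param q False-negative rate.
#' @param r False-positive rate.
#' @param seed Integer seed.
#' @return 0/1 matrix of observed states, same shape.
#' @export
apply_detection_noise <- function(tip_states, q, r, seed = 1L) {
  stopifnot(q >= 0, q <= 1, r >= 0, r <= 1)
  with_substream(seed, "noise", {
    u <- matrix(stats::runif(length(tip_states)), nrow(tip_states))
    observed <- tip_states
    observed[tip_states == 1L & u < q] <- 0L
    observed[tip_states == 0L & u < r] <- 1L
    dimnames(observed) <- dimnames(tip_states)
    observed
  })
}

#' Simulate a seed alignment for a synthetic component
#'
#' Draws a random consensus and `n_seqs` lightly diverged copies, giving
#' a realistic, non-degenerate profile for screen tests.
#'
#' @param component Component name.
#' @param length Consensus length.
#' @param n_seqs Number of aligned copies.
#' @param divergence Per-position substitution probability among copies.
#' @param seed Integer seed.
#' @return A [seed_alignment()].
#' @export
simulate_seed_alignment <- function(component, length = 120L, n_seqs = 5L,
                                    divergence = 0.1, seed = 1L) {
  aa <- aa_alphabet()
  with_substream(seed, paste0("seed_aln:", component), {
    consensus <- sample(aa, length, replace = TRUE)
    seqs <- vapply(seq_len(n_seqs), function(i) {
      s <- consensus
      flip <- stats::runif(length) < divergence
      s[flip] <- sample(aa, sum(flip), replace = TRUE)
      paste(s, collapse = "")
    }, "")
    seed_alignment(component, seqs,
                   source_genomes = paste0("train", seq_len(n_seqs)))
  })
}

#' @noRd
mutate_sequence <- function(sequence, substitution, indel_rate) {
  aa <- aa_alphabet()
  s <- strsplit(sequence, "")[[1]]
  flip <- stats::runif(length(s)) < substitution
  s[flip] <- sample(aa, sum(flip), replace = TRUE)
  if (indel_rate > 0) {
    out <- character(0)
    for (ch in s) {
      if (stats::runif(1) < indel_rate) {
        len <- stats::rgeom(1, 0.5) + 1L  # geometric, mean 2
        if (stats::runif(1) < 0.5) {
          out <- c(out, sample(aa, len, replace = TRUE), ch)  # insertion
        } else if (len < length(out)) {
          out <- out[seq_len(length(out) - len)]              # deletion
          out <- c(out, ch)
        } else out <- c(out, ch)
      } else out <- c(out, ch)
    }
    s <- out
  }
  paste(s, collapse = "")
}

#' @noRd
random_fg_decoy <- function(min_length) {
  spacers <- c("S", "T", "N", "Q", "A", "P")
  units <- character(0)
  while (sum(nchar(units)) < min_length)
    units <- c(units, sample(c("FG", "GLFG", "FSFG"), 1),
               paste(sample(spacers, sample(1:2, 1), replace = TRUE),
                     collapse = ""))
  paste(units, collapse = "")
}

#' @noRd
random_wd_decoy <- function() {
  aa <- aa_alphabet()
  windows <- vapply(1:6, function(i) {
    pre <- paste(sample(aa, 18, replace = TRUE), collapse = "")
    core <- paste0(sample(c("L", "I", "V"), 1),
                   paste(sample(aa, sample(6:12, 1), replace = TRUE),
                         collapse = ""), "WD")
    paste0(pre, core)
  }, "")
  paste(windows, collapse = "")
}

#' Simulate a proteome with planted homologs and repeat decoys
#'
#' For each seed alignment, emits one planted homolog (the consensus
#' mutated at the configured substitution fraction, with geometric
#' indels) plus three decoy classes: shuffled-composition random
#' sequences, FG-repeat-only sequences and WD-repeat-window-only
#' sequences. The truth table records each record's class and source
#' component.
#'
#' @param seeds List of [seed_alignment()] objects.
#' @param config A [simulation_config()].
#' @param genome Genome code for the records.
#' @return A list with `proteome` (a [protein_records()] set) and `truth`
#'   (data frame: `id`, `class`, `component`).
#' @export
simulate_proteome <- function(seeds, config, genome = "synthetic") {
  stopifnot(length(seeds) >= 1, inherits(config, "simulation_config"))
  if (config$substitution > 1) stop("substitution fraction must be <= 1")
  aa <- aa_alphabet()
  with_substream(config$seed, paste0("proteome:", genome), {
    consensus_pool <- unlist(strsplit(vapply(
      seeds, function(s) build_profile(s)$consensus, ""), ""))
    ids <- character(0); seqs <- character(0); cls <- character(0)
    comp <- character(0)
    for (s in seeds) {
      p <- build_profile(s)
      planted <- mutate_sequence(p$consensus, config$substitution,
                                 config$indel_rate)
      ids <- c(ids, paste0("planted_", s$component))
      seqs <- c(seqs, planted); cls <- c(cls, "planted")
      comp <- c(comp, s$component)
    }
    for (i in seq_len(config$n_random)) {
      ids <- c(ids, sprintf("decoy_rnd_%03d", i))
      seqs <- c(seqs, paste(sample(consensus_pool, config$seq_length,
                                   replace = TRUE), collapse = ""))
      cls <- c(cls, "random"); comp <- c(comp, NA_character_)
    }
    for (i in seq_len(config$n_fg)) {
      ids <- c(ids, sprintf("decoy_fg_%03d", i))
      seqs <- c(seqs, random_fg_decoy(config$seq_length))
      cls <- c(cls, "fg"); comp <- c(comp, NA_character_)
    }
    for (i in seq_len(config$n_wd)) {
      ids <- c(ids, sprintf("decoy_wd_%03d", i))
      seqs <- c(seqs, random_wd_decoy())
      cls <- c(cls, "wd"); comp <- c(comp, NA_character_)
    }
    list(proteome = protein_records(ids, genome, seqs),
         truth = data.frame(id = ids, class = cls, component = comp,
                            stringsAsFactors = FALSE))
  })
}

#' Run the full synthetic pipeline and score it against the truth
#'
#' Simulates a tree and single-gain/multiple-loss character evolution,
#' applies detection noise, optionally pushes sequences through the
#' screen (planted homologs for observed presences plus decoys, screened
#' per genome), reconstructs ancestral content by Dollo parsimony on the
#' true topology, and scores the result: ancestral-complement recall and
#' precision and the gain-edge recovery rate. Deterministic per seed.
#'
#' @param config A [simulation_config()].
#' @param with_sequences If `TRUE`, derive the observed matrix through the
#'   sequence screen instead of using the noisy states directly (slower;
#'   keep `n_components` and `n_leaves` small).
#' @return A list of class `scenario_result` with `truth`, `observed`
#'   (matrix), `dollo`, and `scorecard` (list: `leca_recall`,
#'   `leca_precision`, `gain_edge_recovery`, `n_components`).
#' @export
end_to_end_scenario <- function(config, with_sequences = FALSE) {
  tree <- simulate_tree(config$n_leaves, config$seed)
  truth <- simulate_dollo_evolution(tree, config)
  observed <- apply_detection_noise(truth$tip_states, config$q, config$r,
                                    config$seed)
  if (with_sequences) {
    comps <- rownames(observed)
    seeds <- lapply(comps, function(cn)
      simulate_seed_alignment(cn, length = 60, seed = config$seed))
    names(seeds) <- comps
    profiles <- lapply(seeds, build_profile)
    called <- observed * 0L
    for (g in colnames(observed)) {
      keep <- comps[observed[, g] == 1L]
      sim <- simulate_proteome(seeds[comps], config, genome = g)
      pr <- sim$proteome
      pr <- pr[pr$id %in% c(paste0("planted_", keep),
                            sim$truth$id[sim$truth$class != "planted"]), ,
               drop = FALSE]
      hits <- screen_proteome(profiles, pr,
                              threshold = screen_null_threshold(profiles,
                                                                config))
      dec <- apply_vetting(hits, pr)
      acc <- dec[dec$status == "accepted", , drop = FALSE]
      called[unique(acc$component), g] <- 1L
    }
    observed <- called
  }
  dollo <- dollo_reconstruct(tree, observed)
  est_leca <- dollo$component[dollo$root_state == "present"]
  true_leca <- names(truth$gain_edges)[truth$gain_edges == "root" &
                                         rowSums(truth$tip_states) > 0]
  recovered <- sum(dollo$gain_edge == truth$gain_edges[dollo$component],
                   na.rm = TRUE)
  informative <- sum(!is.na(dollo$gain_edge))
  scorecard <- list(
    leca_recall = if (length(true_leca))
      length(intersect(est_leca, true_leca)) / length(true_leca) else NA,
    leca_precision = if (length(est_leca))
      length(intersect(est_leca, true_leca)) / length(est_leca) else NA,
    gain_edge_recovery = if (informative) recovered / informative else NA,
    n_components = config$n_components)
  structure(list(truth = truth, observed = observed, dollo = dollo,
                 scorecard = scorecard), class = "scenario_result")
}

#' @noRd
screen_null_threshold <- function(profiles, config) {
  # decoy-quantile threshold from a dedicated null proteome
  null_prot <- with_substream(config$seed, "null_decoys", {
    aa <- aa_alphabet()
    protein_records(sprintf("null_%03d", 1:50), "null",
                    vapply(1:50, function(i)
                      paste(sample(aa, config$seq_length, replace = TRUE),
                            collapse = ""), ""))
  })
  scores <- unlist(lapply(profiles, function(p)
    vapply(null_prot$sequence, function(s)
      score_sequence(p, s)$score, numeric(1))))
  unname(stats::quantile(scores, 0.99))
}

#' @export
print.scenario_result <- function(x, ...) {
  sc <- x$scorecard
  cat(sprintf(paste0("synthetic scenario: %d components; LECA recall %.3f, ",
                     "precision %.3f, gain-edge recovery %.3f\n"),
              sc$n_components, sc$leca_recall, sc$leca_precision,
              sc$gain_edge_recovery))
  invisible(x)
}
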