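# Independent oracles used across the suite. These deliberately take a
# different algorithmic route from the package implementation.

# Match-anchored alignment oracle: best score over all alignment paths,
# formulated as "best path ending with column i matched to sequence
# position j", with gap runs costed in closed form between consecutive
# matches. Independent of the three-state DP in the package.
oracle_align <- function(profile, sequence, mode = profile$mode) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(sequence, "")[[1]]
  L <- nrow(profile$scores); N <- length(chars)
  go <- profile$gap_open; ge <- profile$gap_extend
  s <- function(i, j) {
    k <- match(chars[j], aa)
    if (is.na(k)) 0 else profile$scores[i, k]
  }
  del_cost <- function(from, to) {  # skip columns from..to (may be empty)
    if (to < from) return(0)
    go[from] + if (to > from) sum(ge[(from + 1):to]) else 0
  }
  lead_cost <- function(k) if (k < 1) 0 else del_cost(1, k)
  B <- matrix(-Inf, L, N)
  for (j in seq_len(N)) {
    for (i in seq_len(L)) {
      start_term <- if (mode == "local") 0
                    else if (i == 1) 0 else -lead_cost(i - 1)
      best_prev <- start_term
      if (j > 1) {
        if (i > 1 && B[i - 1, j - 1] > best_prev)
          best_prev <- B[i - 1, j - 1]
        if (i > 2)
          for (k in seq_len(i - 2))
            best_prev <- max(best_prev, B[k, j - 1] - del_cost(k + 1, i - 1))
        if (i > 1 && j > 2)
          for (l in seq_len(j - 2))
            best_prev <- max(best_prev,
                             B[i - 1, l] - (go[i - 1] + (j - l - 2) * ge[i - 1]))
      }
      B[i, j] <- s(i, j) + best_prev
    }
  }
  if (mode == "local") return(max(B))
  best <- -del_cost(1, L)   # the degenerate path deleting every column
  for (j in seq_len(N)) {
    best <- max(best, B[L, j])
    if (L > 1)
      for (k in seq_len(L - 1))
        best <- max(best, B[k, j] - del_cost(k + 1, L))
  }
  best
}

# Exhaustive enumeration over internal-node state assignments. Events are
# counted per edge (parent != child); a gain on the root stem is counted
# when the root is in state 1. Returns the minimum cost over assignments
# with exactly one gain (Dollo) and, separately, per-root-state minima of
# plain state changes (unrestricted parsimony, no stem).
oracle_parsimony <- function(tree, states) {
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  states <- as.integer(states[tree$tip.label])
  edges <- tree$edge
  best_dollo <- Inf; best_dollo_root <- NA
  changes_root <- c(`0` = Inf, `1` = Inf)
  for (mask in 0:(2^n_int - 1)) {
    assign <- c(states, as.integer(intToBits(mask))[seq_len(n_int)])
    gains <- sum(assign[edges[, 1]] == 0 & assign[edges[, 2]] == 1)
    losses <- sum(assign[edges[, 1]] == 1 & assign[edges[, 2]] == 0)
    root_state <- assign[n_tip + 1]
    stem_gains <- gains + root_state   # character must arise somewhere
    if (stem_gains == 1 && stem_gains + losses < best_dollo) {
      best_dollo <- stem_gains + losses
      best_dollo_root <- root_state
    }
    key <- as.character(root_state)
    changes_root[key] <- min(changes_root[key], gains + losses)
  }
  list(dollo_cost = best_dollo, dollo_root = best_dollo_root,
       changes_root0 = unname(changes_root["0"]),
       changes_root1 = unname(changes_root["1"]))
}

# Naive per-supergroup recount, straight off the definitions.
oracle_supergroup_counts <- function(m, taxonomy) {
  sg <- setNames(taxonomy$supergroup, taxonomy$genome)
  universe <- attr(taxonomy, "universe")
  sapply(universe, function(g) {
    cols <- names(sg)[sg == g]
    cols <- intersect(cols, colnames(m$states))
    sum(sapply(rownames(m$states), function(cn)
      any(m$states[cn, cols] == 1)))
  })
}

# Brute-force two-sided exact p-value over all margin-preserving tables,
# via hypergeometric probabilities computed from binomial coefficients.
oracle_exact_pvalue <- function(tab) {
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  prob <- function(a) choose(m1, a) * choose(m2, k - a) / choose(m1 + m2, k)
  support <- max(0, k - m2):min(k, m1)
  p_obs <- prob(tab[1, 1])
  sum(sapply(support, prob)[sapply(support, prob) <= p_obs * (1 + 1e-7)])
}

random_presence_matrix <- function(n_comp, genomes, p = 0.5) {
  presence_matrix(matrix(rbinom(n_comp * length(genomes), 1, p), n_comp,
                         dimnames = list(sprintf("c%02d", seq_len(n_comp)),
                                         genomes)))
}

random_taxonomy <- function(genomes, universe = supergroup_universe()) {
  taxonomy_map(genomes, class = rep("cls", length(genomes)),
               supergroup = sample(universe, length(genomes), replace = TRUE),
               universe = universe)
}

random_profile <- function(len, seed, gap_open = 4, gap_extend = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- replicate(3, paste(sample(aa, len, replace = TRUE), collapse = ""))
  build_profile(seed_alignment(sprintf("rnd%d", seed), seqs),
                gap_open = gap_open, gap_extend = gap_extend)
}

random_aa_seq <- function(len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
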