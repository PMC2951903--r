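#' Rooting specifications for the eukaryote tree
#'
#' The position of the eukaryote root is uncertain, so ancestral
#' reconstructions are reported under alternative rootings:
#'
#' * `excavate_basal`: Excavates are the outgroup; root bipartition
#'   \{Excavates\} | \{others\}.
#' * `unikont_bikont`: root between \{Opisthokonts, Amoebozoa\} and
#'   \{Plantae, Chromalveolates, Excavates\}.
#' * `star`: a fully unresolved rake of the five supergroups; it only
#'   supports bounds on the ancestral complement (see
#'   [star_tree_bounds()]).
#' * `custom`: any rooted Newick topology over the matrix leaves.
#'
#' Within each side of the root the arrangement is fixed to a default
#' resolution; root-level results (the LECA complement) depend only on
#' the root bipartition.
#'
#' @param preset One of `"excavate_basal"`, `"unikont_bikont"`, `"star"`,
#'   `"custom"`.
#' @param newick Newick string (with trailing `;`) when `preset` is
#'   `"custom"`.
#' @return An object of class `rooting_spec`.
#' @export
rooting_spec <- function(preset = c("unikont_bikont", "excavate_basal",
                                    "star", "custom"), newick = NULL) {
  preset <- match.arg(preset)
  if (preset == "custom" && is.null(newick))
    stop("custom rooting requires a newick string")
  structure(list(preset = preset, newick = newick), class = "rooting_spec")
}

#' Resolve a rooting specification to a rooted topology
#'
#' @param spec A [rooting_spec()] or a preset name.
#' @param leaves Leaf labels the topology must cover (for presets, the
#'   five supergroups must all be among them).
#' @return An `ape::phylo` rooted topology.
#' @export
rooting_topology <- function(spec, leaves = supergroup_universe()) {
  if (is.character(spec)) spec <- rooting_spec(spec)
  txt <- switch(spec$preset,
    unikont_bikont =
      "((Opisthokonts,Amoebozoa),(Plantae,(Chromalveolates,Excavates)));",
    excavate_basal =
      "(Excavates,((Opisthokonts,Amoebozoa),(Plantae,Chromalveolates)));",
    star =
      "(Opisthokonts,Amoebozoa,Plantae,Chromalveolates,Excavates);",
    custom = spec$newick)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse rooting topology")
  missing <- setdiff(leaves, tree$tip.label)
  if (spec$preset != "custom" && length(setdiff(tree$tip.label, leaves)))
    stop("supergroup missing from topology: ",
         paste(setdiff(tree$tip.label, leaves), collapse = ", "))
  tree
}

#' @noRd
tree_children <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

#' @noRd
clade_label <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  tips <- ape::extract.clade(tree, node)$tip.label
  paste(sort(tips), collapse = "+")
}

#' Dollo parsimony reconstruction of binary characters
#'
#' Reconstructs each component's history under a single-gain, multiple-
#' loss model: the gain is placed on the edge above the last common
#' ancestor of all present leaves (the root's stem when that ancestor is
#' the root), and losses are the maximal all-absent clades strictly below
#' the gain. The parsimony cost is 1 gain plus the number of losses. The
#' root state is `present` exactly when the gain maps to the root stem.
#' Multifurcating nodes are supported.
#'
#' @param topology A rooted `ape::phylo` tree.
#' @param tip_states A 0/1 matrix with components as rows and tree leaves
#'   as columns (a named 0/1 vector is treated as a single component named
#'   `"component"`). Every leaf must have a state.
#' @return A data frame of class `dollo_result` with columns `component`,
#'   `gain_edge` (child-clade label, or `"root"`), `root_state`
#'   (`"present"`/`"absent"`), `n_losses`, `cost`, `ambiguous` (`NA` until
#'   [mark_ambiguous()] is applied) and a list column `loss_edges`.
#'   Components present at no leaf get `gain_edge = NA` and cost 0.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),C);")
#' dollo_reconstruct(tr, c(A = 1, B = 0, C = 0))
#' @export
dollo_reconstruct <- function(topology, tip_states) {
  if (is.null(dim(tip_states)))
    tip_states <- matrix(tip_states, nrow = 1,
                         dimnames = list("component", names(tip_states)))
  n_tip <- ape::Ntip(topology)
  if (!setequal(colnames(tip_states), topology$tip.label) ||
      anyNA(tip_states))
    stop("every leaf needs a 0/1 state")
  tip_states <- tip_states[, topology$tip.label, drop = FALSE]
  kids <- tree_children(topology)
  root <- n_tip + 1L
  post <- rev(unique(tree_preorder(topology)))
  rows <- lapply(seq_len(nrow(tip_states)), function(i) {
    st <- as.integer(tip_states[i, ])
    n_below <- integer(n_tip + topology$Nnode)
    n_below[seq_len(n_tip)] <- st
    for (nd in post)
      if (nd > n_tip) n_below[nd] <- sum(n_below[kids[[nd]]])
    if (n_below[root] == 0L)
      return(list(component = rownames(tip_states)[i], gain_edge = NA_character_,
                  root_state = "absent", n_losses = 0L, cost = 0L,
                  loss_edges = character(0)))
    present_tips <- which(st == 1L)
    gain_node <- if (length(present_tips) == 1L) present_tips else
      ape::getMRCA(topology, topology$tip.label[present_tips])
    loss <- character(0)
    if (gain_node > n_tip) {
      stack <- gain_node
      while (length(stack)) {
        nd <- stack[1]; stack <- stack[-1]
        for (ch in kids[[nd]]) {
          if (n_below[ch] == 0L) loss <- c(loss, clade_label(topology, ch))
          else if (ch > n_tip) stack <- c(stack, ch)
        }
      }
    }
    loss <- sort(loss)
    list(component = rownames(tip_states)[i],
         gain_edge = if (gain_node == root) "root"
                     else clade_label(topology, gain_node),
         root_state = if (gain_node == root) "present" else "absent",
         n_losses = length(loss), cost = 1L + length(loss),
         loss_edges = loss)
  })
  out <- data.frame(component = vapply(rows, `[[`, "", "component"),
                    gain_edge = vapply(rows, `[[`, "", "gain_edge"),
                    root_state = vapply(rows, `[[`, "", "root_state"),
                    n_losses = vapply(rows, `[[`, 0L, "n_losses"),
                    cost = vapply(rows, `[[`, 0L, "cost"),
                    ambiguous = NA, stringsAsFactors = FALSE)
  out$loss_edges <- lapply(rows, `[[`, "loss_edges")
  structure(out, class = c("dollo_result", "data.frame"))
}

#' @noRd
tree_preorder <- function(tree) {
  # node order root -> leaves, by walking edges of the (arbitrary) edge
  # matrix repeatedly; returns nodes in an order where parents precede
  # children.
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  kids <- tree_children(tree)
  order <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    order <- c(order, nd)
    if (nd > n_tip) stack <- c(kids[[nd]], stack)
  }
  order
}

#' Minimum state changes under unrestricted binary parsimony
#'
#' Unit-cost Sankoff dynamic programme over a rooted (possibly
#' multifurcating) topology, with the root state fixed.
#'
#' @param topology A rooted `ape::phylo`.
#' @param states Named 0/1 vector over the leaves.
#' @param root_state 0 or 1.
#' @return Integer: the minimum number of state-changing edges.
#' @export
parsimony_changes <- function(topology, states, root_state) {
  n_tip <- ape::Ntip(topology)
  states <- states[topology$tip.label]
  kids <- tree_children(topology)
  inf <- .Machine$integer.max %/% 4L
  cost <- matrix(inf, n_tip + topology$Nnode, 2)
  cost[cbind(seq_len(n_tip), as.integer(states) + 1L)] <- 0L
  for (nd in rev(tree_preorder(topology))) {
    if (nd <= n_tip) next
    for (s in 0:1)
      cost[nd, s + 1] <- sum(vapply(kids[[nd]], function(ch)
        min(cost[ch, s + 1], cost[ch, 2 - s] + 1L), numeric(1)))
  }
  as.integer(cost[n_tip + 1L, root_state + 1])
}

#' Flag components whose root state is ambiguous
#'
#' A component's Dollo root state is flagged as ambiguous when an
#' unrestricted binary parsimony mapping (gains and losses both allowed at
#' unit cost) attains a cost no greater than the Dollo cost while
#' assigning the opposite state to the root — i.e. the root state is not
#' uniquely determined at minimal cost. This mirrors the "(?)" convention
#' of gain/loss figures.
#'
#' @inheritParams dollo_reconstruct
#' @param dollo The [dollo_reconstruct()] result for the same inputs.
#' @return `dollo` with the `ambiguous` column filled in.
#' @export
mark_ambiguous <- function(topology, tip_states, dollo) {
  if (is.null(dim(tip_states)))
    tip_states <- matrix(tip_states, nrow = 1,
                         dimnames = list("component", names(tip_states)))
  flags <- vapply(seq_len(nrow(dollo)), function(i) {
    if (is.na(dollo$gain_edge[i])) return(FALSE)
    st <- tip_states[dollo$component[i], ]
    opposite <- if (dollo$root_state[i] == "present") 0L else 1L
    parsimony_changes(topology, st, opposite) <= dollo$cost[i]
  }, logical(1))
  dollo$ambiguous <- flags
  dollo
}

#' Ancestral (LECA) complement under a rooting
#'
#' For a binary-rooted preset or custom topology, the LECA complement is
#' the set of components whose Dollo root state is `present` —
#' equivalently, for binary-rooted trees, those present on both sides of
#' the root bipartition. For the `star` preset only bounds are defined and
#' the [star_tree_bounds()] result is returned instead.
#'
#' @param m A genome-level [presence_matrix()].
#' @param taxonomy The matching [taxonomy_map()].
#' @param rooting A [rooting_spec()] or preset name.
#' @return Character vector of component names (binary rootings), or the
#'   bounds object from [star_tree_bounds()] (star).
#' @examples
#' m <- load_fixture("nup_table2")
#' length(leca_complement(m, fixture_taxonomy(m), "unikont_bikont"))
#' @export
leca_complement <- function(m, taxonomy, rooting = "unikont_bikont") {
  if (is.character(rooting)) rooting <- rooting_spec(rooting)
  if (rooting$preset == "star") return(star_tree_bounds(m, taxonomy))
  sgm <- collapse_to_supergroups(m, taxonomy)
  tree <- rooting_topology(rooting, leaves = matrix_genomes(sgm))
  missing <- setdiff(matrix_genomes(sgm), tree$tip.label)
  if (length(missing))
    stop("supergroup missing from topology: ",
         paste(missing, collapse = ", "))
  # supergroups absent from the matrix but present in the tree score 0
  states <- matrix(0L, nrow(sgm$states), length(tree$tip.label),
                   dimnames = list(matrix_components(sgm), tree$tip.label))
  states[, matrix_genomes(sgm)] <- sgm$states
  d <- dollo_reconstruct(tree, states)
  d$component[d$root_state == "present"]
}

#' Star-tree bounds on the ancestral complement
#'
#' With the supergroup relationships left unresolved, the ancestral
#' complement can still be bracketed: the lower bound is the number of
#' components present in every supergroup, the upper bound the minimum
#' over supergroups of the per-supergroup component count (with the
#' witnessing supergroup reported).
#'
#' @inheritParams leca_complement
#' @return A list of class `star_bounds` with `lower`, `upper`,
#'   `witness`, and the underlying `universal` set and `counts`.
#' @export
star_tree_bounds <- function(m, taxonomy) {
  counts <- supergroup_counts(m, taxonomy)
  universal <- universal_components(m, taxonomy)
  witness <- names(counts)[which.min(counts)]
  structure(list(lower = length(universal), upper = unname(min(counts)),
                 witness = witness, universal = universal, counts = counts),
            class = "star_bounds")
}

#' @export
print.star_bounds <- function(x, ...) {
  cat(sprintf("star-tree bounds on the ancestral complement: [%d, %d]\n",
              x$lower, x$upper))
  cat(sprintf("  lower: components present in every supergroup\n"))
  cat(sprintf("  upper: smallest per-supergroup count (%s)\n", x$witness))
  invisible(x)
}

#' Summarise gains and losses by lineage
#'
#' Groups the per-component Dollo events by the lineage (edge, labelled by
#' its child clade) they map to, and lists the LECA complement (root-state
#' present components).
#'
#' @param dollo A [dollo_reconstruct()] result, optionally with ambiguity
#'   flags from [mark_ambiguous()].
#' @return A list of class `event_summary` with `leca` (character),
#'   `gains` and `losses` (data frames with columns `lineage`,
#'   `component`), and `ambiguous` (character).
#' @export
gain_loss_summary <- function(dollo) {
  stopifnot(inherits(dollo, "dollo_result"))
  present <- !is.na(dollo$gain_edge)
  leca <- dollo$component[present & dollo$root_state == "present"]
  gained <- dollo[present & dollo$root_state == "absent", , drop = FALSE]
  gains <- data.frame(lineage = gained$gain_edge,
                      component = gained$component, stringsAsFactors = FALSE)
  losses <- do.call(rbind, lapply(which(present), function(i) {
    le <- dollo$loss_edges[[i]]
    if (!length(le)) return(NULL)
    data.frame(lineage = le, component = dollo$component[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(losses))
    losses <- data.frame(lineage = character(0), component = character(0))
  amb <- dollo$component[present & !is.na(dollo$ambiguous) & dollo$ambiguous]
  structure(list(leca = leca, gains = gains, losses = losses,
                 ambiguous = amb),
            class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("LECA complement: %d components\n", length(x$leca)))
  cat(sprintf("post-root gains: %d; losses: %d; ambiguous root states: %d\n",
              nrow(x$gains), nrow(x$losses), length(x$ambiguous)))
  invisible(x)
}
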