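# Dollo parsimony on rooted species trees.
#
# Under Dollo's assumption a gene is invented once and never regained, so the
# most parsimonious history of an observed presence/absence profile places
# the gain at the last common ancestor of all presence leaves and one loss on
# each maximal subtree below it that contains no presence leaf. Trees are ape
# "phylo" objects; polytomies are handled as-is, without arbitrary
# resolution.

.tree_root <- function(tree) {
  setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
}

.tree_parent <- function(tree) {
  n_nodes <- max(tree$edge)
  parent <- rep(NA_integer_, n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

# logical vector over all node ids: does the subtree at the node contain any
# presence tip? (postorder accumulation)
.any_presence <- function(tree, pres_tip_ids) {
  n_nodes <- max(tree$edge)
  anyp <- rep(FALSE, n_nodes)
  anyp[pres_tip_ids] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    if (anyp[po[i, 2]]) anyp[po[i, 1]] <- TRUE
  anyp
}

# logical vector over all node ids: is the node inside (or equal to) the
# subtree rooted at `node`? (preorder propagation)
.in_subtree <- function(tree, node) {
  n_nodes <- max(tree$edge)
  inside <- rep(FALSE, n_nodes)
  inside[node] <- TRUE
  pr <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(pr))))
    if (inside[pr[i, 1]]) inside[pr[i, 2]] <- TRUE
  inside
}

.node_labels <- function(tree, nodes) {
  n_tip <- length(tree$tip.label)
  vapply(nodes, function(v) {
    if (v <= n_tip) return(tree$tip.label[v])
    lab <- tree$node.label[v - n_tip]
    if (!is.null(lab) && !is.na(lab) && nzchar(lab)) lab else paste0("node", v)
  }, character(1))
}

.match_profile_tree <- function(profile, tree) {
  if (!setequal(profile$codes, tree$tip.label))
    stop("profile catalog and tree leaf set differ")
  profile$presence[tree$tip.label]
}

#' Dollo-parsimony reconstruction of a gene's history
#'
#' Infers, for one phylogenetic profile on a rooted species tree, the single
#' gain node (the last common ancestor of all species carrying the gene) and
#' the minimal set of loss events: one loss per maximal subtree below the
#' origin that entirely lacks the gene. A gene whose origin is the tree root
#' is called ancestral (present in the last common ancestor of all species
#' in the tree — LECA when the tree spans the eukaryotes).
#'
#' @param profile A [phylo_profile()] with at least one presence; its catalog
#'   must equal the tree leaf set.
#' @param tree Rooted `ape::phylo` species tree (polytomies allowed).
#' @return Object of class `"dollo_reconstruction"`: `protein_name`,
#'   `origin` (node id) and `origin_label`, `losses` (node ids of the pruned
#'   branches' child nodes) and `loss_labels`, `loss_count`, and logical
#'   `leca`. Replaying gain-at-origin plus the losses reproduces the input
#'   presence vector exactly.
#' @examples
#' tree <- ape::read.tree(text = "((A_sp1,B_sp1),(C_sp1,D_sp1));")
#' tree$tip.label <- c("Aaaa", "Bbbb", "Cccc", "Dddd")
#' cat4 <- catalog_from_tree(tree)
#' p <- phylo_profile("g", c(1, 0, 1, 0), cat4)
#' dollo_reconstruct(p, tree)
#' @export
dollo_reconstruct <- function(profile, tree) {
  stopifnot(inherits(profile, "phylo_profile"), inherits(tree, "phylo"))
  pres <- .match_profile_tree(profile, tree)
  pres_ids <- unname(which(pres == 1L))
  if (length(pres_ids) == 0)
    stop("all-absent profile for '", profile$protein_name,
         "': no origin definable under a single-gain model")
  root <- .tree_root(tree)
  origin <- if (length(pres_ids) == 1) pres_ids else ape::getMRCA(tree, pres_ids)
  anyp <- .any_presence(tree, pres_ids)
  inside <- .in_subtree(tree, origin)
  parent <- .tree_parent(tree)
  # maximal absent subtrees below the origin: absent node whose parent is an
  # any-presence node inside the origin subtree
  nodes <- seq_len(max(tree$edge))
  losses <- nodes[!anyp[nodes] & !is.na(parent[nodes]) &
                    inside[parent[nodes]] & anyp[parent[nodes]]]
  structure(list(protein_name = profile$protein_name,
                 origin = origin,
                 origin_label = .node_labels(tree, origin),
                 losses = losses,
                 loss_labels = .node_labels(tree, losses),
                 loss_count = length(losses),
                 leca = origin == root),
            class = "dollo_reconstruction")
}

#' @export
print.dollo_reconstruction <- function(x, ...) {
  cat("Dollo reconstruction of", x$protein_name, "\n")
  cat("  origin:", x$origin_label,
      if (x$leca) "(tree root: ancestral)" else "", "\n")
  cat("  losses:", x$loss_count,
      if (x$loss_count > 0)
        paste0("(", paste(x$loss_labels, collapse = ", "), ")") else "", "\n")
  invisible(x)
}

#' Replay a gain/loss history into a presence vector
#'
#' Simulates the deterministic replay of a reconstruction (or simulated
#' truth): the gene is present at every leaf below `origin` except those
#' under a loss node.
#'
#' @param tree Rooted `ape::phylo`.
#' @param origin Node id of the gain.
#' @param losses Integer node ids of pruned branches (child nodes).
#' @return Named 0/1 integer vector over `tree$tip.label`.
#' @export
replay_presence <- function(tree, origin, losses = integer(0)) {
  inside <- .in_subtree(tree, origin)
  for (v in losses) inside <- inside & !.in_subtree(tree, v)
  n_tip <- length(tree$tip.label)
  stats::setNames(as.integer(inside[seq_len(n_tip)]), tree$tip.label)
}

#' Exhaustive minimal-loss search (test oracle)
#'
#' Independent brute-force counterpart of [dollo_reconstruct()]: enumerates
#' every node as a candidate gain, keeps those whose subtree contains all
#' presence leaves, computes each candidate's minimal loss set by recursive
#' pruning, and returns the optimum (fewest losses; ties resolved toward the
#' most recent candidate, i.e. smallest subtree). Restricted to small trees.
#'
#' @param profile A [phylo_profile()] with >= 1 presence.
#' @param tree Rooted `ape::phylo` with at most `max_leaves` leaves.
#' @param max_leaves Exhaustive-search size guard (default 12).
#' @return List with `origin` (node id) and `loss_count`.
#' @export
brute_force_min_losses <- function(profile, tree, max_leaves = 12) {
  stopifnot(inherits(profile, "phylo_profile"), inherits(tree, "phylo"))
  if (length(tree$tip.label) > max_leaves)
    stop("tree too large for exhaustive search (> ", max_leaves, " leaves)")
  pres <- .match_profile_tree(profile, tree)
  pres_ids <- unname(which(pres == 1L))
  if (length(pres_ids) == 0) stop("all-absent profile")
  children <- split(tree$edge[, 2], tree$edge[, 1])
  n_tip <- length(tree$tip.label)

  has_pres <- function(v) {
    if (v <= n_tip) return(v %in% pres_ids)
    any(vapply(children[[as.character(v)]], has_pres, logical(1)))
  }
  tips_under <- function(v) {
    if (v <= n_tip) return(v)
    unlist(lapply(children[[as.character(v)]], tips_under))
  }
  min_losses_below <- function(v) {
    if (!has_pres(v)) return(1L)      # prune the whole subtree: one loss
    if (v <= n_tip) return(0L)        # presence leaf, nothing to do
    sum(vapply(children[[as.character(v)]], min_losses_below, integer(1)))
  }

  best <- NULL
  for (g in seq_len(max(tree$edge))) {
    tips <- tips_under(g)
    if (!all(pres_ids %in% tips)) next
    cost <- if (g <= n_tip) 0L else
      sum(vapply(children[[as.character(g)]], min_losses_below, integer(1)))
    if (is.null(best) || cost < best$loss_count ||
        (cost == best$loss_count && length(tips) < best$n_tips))
      best <- list(origin = g, loss_count = cost, n_tips = length(tips))
  }
  best[c("origin", "loss_count")]
}

#' Count presence/absence transitions along a profile
#'
#' The number of adjacent state changes (present to absent or absent to
#' present) along the profile. Because the catalog order should follow the
#' species tree's leaf order, species relatedness makes this a simple
#' measure of a protein's evolutionary volatility.
#'
#' @param profile A [phylo_profile()] or binary vector.
#' @return Integer transition count.
#' @examples
#' transitions(c(1, 1, 0, 0, 1))  # 2
#' @export
transitions <- function(profile) {
  p <- .as_presence(profile)
  if (length(p) < 1) stop("empty profile")
  if (length(p) == 1) return(0L)
  sum(p[-1] != p[-length(p)])
}

#' Mean loss count over ancestral proteins
#'
#' Averages Dollo loss counts over a protein subset, restricted to proteins
#' inferred ancestral (origin at the tree root), since loss counts of later
#' inventions are not comparable to those of root-origin genes.
#'
#' @param reconstructions List of [dollo_reconstruct()] results.
#' @param subset Optional character vector of protein names; default all.
#' @return Mean loss count (numeric).
#' @export
mean_loss_count <- function(reconstructions, subset = NULL) {
  stopifnot(all(vapply(reconstructions, inherits, logical(1),
                       "dollo_reconstruction")))
  nm <- vapply(reconstructions, function(x) x$protein_name, character(1))
  if (!is.null(subset)) {
    missing <- setdiff(subset, nm)
    if (length(missing) > 0)
      stop("unknown proteins in subset: ", paste(missing, collapse = ", "))
    reconstructions <- reconstructions[nm %in% subset]
  }
  leca <- vapply(reconstructions, function(x) x$leca, logical(1))
  if (!any(leca))
    stop("no ancestral (root-origin) protein in the requested subset")
  mean(vapply(reconstructions[leca], function(x) x$loss_count, numeric(1)))
}

#' Tabulated Dollo report for a profile set
#'
#' @param profiles List of [phylo_profile()] sharing the tree's leaf set.
#' @param tree Rooted `ape::phylo`.
#' @return Data frame: protein, origin label, loss_count, leca, transitions
#'   (profiles reordered to the tree's tip order for the transition count).
#' @export
dollo_report <- function(profiles, tree) {
  recs <- lapply(profiles, dollo_reconstruct, tree = tree)
  data.frame(
    protein = vapply(recs, function(x) x$protein_name, character(1)),
    origin = vapply(recs, function(x) x$origin_label, character(1)),
    loss_count = vapply(recs, function(x) x$loss_count, integer(1)),
    leca = vapply(recs, function(x) x$leca, logical(1)),
    transitions = vapply(profiles, function(p)
      transitions(p$presence[tree$tip.label]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
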