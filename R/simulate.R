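# Seeded gene-content simulator.
#
# The generative model mirrors the assumption behind Dollo parsimony: a gene
# is invented once at an origin node of a rooted species tree and each
# descending lineage loses it on a branch with a fixed per-branch
# probability; a lost gene is never regained. On top of single-gene
# histories the simulator produces co-evolving pairs (losses of one gene
# copied to its partner with a coupling probability), multifunctional
# triplets (an enzyme retained iff at least one of two partners is present)
# and sequence fixtures with a planted interaction motif, all with recorded
# ground truth. Every simulate_* function is a pure function of
# (tree, config, seed).

.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the gene-content simulator. The
#' defaults describe the study conditions the package's analyses target: 90
#' species, 70 genes, per-branch loss probability 0.15, loss coupling 0.9
#' within interacting pairs, noise-free motifs, and 200-residue sequences.
#'
#' @param n_species Number of species (>= 4).
#' @param seed Base random seed (integer).
#' @param origin_policy `"root"`, `"uniform_internal"`, or a fixed node id.
#' @param loss_prob Per-branch loss probability in `[0, 1]`.
#' @param n_genes Number of independent genes to simulate (>= 1).
#' @param coupling Probability that a loss of one pair member co-occurs on
#'   its partner, in `[0, 1]`.
#' @param motif_noise Per-species probability of a motif miscall in `[0, 1]`.
#' @param sequence_length Length of emitted amino-acid sequences.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_species = 90, seed = 1,
                              origin_policy = "root", loss_prob = 0.15,
                              n_genes = 70, coupling = 0.9,
                              motif_noise = 0, sequence_length = 200) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop("`", nm, "` must be a probability in [0, 1]")
  }
  if (!is.numeric(n_species) || n_species < 4)
    stop("`n_species` must be >= 4")
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("`n_genes` must be >= 1")
  chk_prob(loss_prob, "loss_prob")
  chk_prob(coupling, "coupling")
  chk_prob(motif_noise, "motif_noise")
  if (!is.character(origin_policy) && !is.numeric(origin_policy))
    stop("`origin_policy` must be \"root\", \"uniform_internal\" or a node id")
  if (is.character(origin_policy) &&
      !origin_policy %in% c("root", "uniform_internal"))
    stop("unknown origin policy: ", origin_policy)
  if (!is.numeric(sequence_length) || sequence_length < 60)
    stop("`sequence_length` must be >= 60 (to host a planted motif)")
  structure(list(n_species = as.integer(n_species), seed = as.integer(seed),
                 origin_policy = origin_policy, loss_prob = loss_prob,
                 n_genes = as.integer(n_genes), coupling = coupling,
                 motif_noise = motif_noise,
                 sequence_length = as.integer(sequence_length)),
            class = "simulation_config")
}

#' Simulate a rooted binary species tree with code-style leaf names
#'
#' Draws a random rooted binary topology (no branch lengths; losses are
#' per-branch) and labels the leaves with collision-free 4-letter species
#' codes. Deterministic given the seed.
#'
#' @param n_species Number of leaves (>= 4).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree.
#' @export
simulate_species_tree <- function(n_species, seed) {
  if (!is.numeric(n_species) || n_species < 4)
    stop("`n_species` must be >= 4")
  .with_seed(seed, {
    tree <- ape::rtree(as.integer(n_species), rooted = TRUE, br = NULL)
    codes <- character(0)
    while (length(codes) < n_species) {
      cand <- paste0(sample(LETTERS, 1),
                     paste(sample(letters, 3, replace = TRUE), collapse = ""))
      if (!(cand %in% codes)) codes <- c(codes, cand)
    }
    tree$tip.label <- codes
    tree
  })
}

.choose_origin <- function(tree, policy) {
  n_tip <- length(tree$tip.label)
  if (is.numeric(policy)) {
    if (policy < 1 || policy > max(tree$edge)) stop("fixed origin not a node id")
    return(as.integer(policy))
  }
  switch(policy,
         root = .tree_root(tree),
         uniform_internal = {
           internals <- (n_tip + 1L):max(tree$edge)
           internals[sample.int(length(internals), 1)]
         })
}

# one stochastic descent from `origin`: per-branch loss with prob loss_prob,
# no events below a loss (the gene is already gone there)
.draw_history <- function(tree, origin, loss_prob) {
  children <- split(tree$edge[, 2], tree$edge[, 1])
  n_tip <- length(tree$tip.label)
  pres <- integer(n_tip)
  losses <- integer(0)
  recurse <- function(v) {
    if (v <= n_tip) {
      pres[v] <<- 1L
      return(invisible(NULL))
    }
    for (ch in children[[as.character(v)]]) {
      if (stats::runif(1) < loss_prob) losses <<- c(losses, ch)
      else recurse(ch)
    }
  }
  recurse(origin)
  list(presence = stats::setNames(pres, tree$tip.label), losses = losses)
}

# descent coupled to partner losses: on a branch where the partner lost the
# gene, loss is copied with prob `coupling`; everywhere a residual
# independent loss at rate loss_prob * (1 - coupling) applies
.draw_coupled <- function(tree, origin, partner_losses, loss_prob, coupling) {
  children <- split(tree$edge[, 2], tree$edge[, 1])
  n_tip <- length(tree$tip.label)
  pres <- integer(n_tip)
  losses <- integer(0)
  recurse <- function(v) {
    if (v <= n_tip) {
      pres[v] <<- 1L
      return(invisible(NULL))
    }
    for (ch in children[[as.character(v)]]) {
      lost <- (ch %in% partner_losses) && stats::runif(1) < coupling
      if (!lost) lost <- stats::runif(1) < loss_prob * (1 - coupling)
      if (lost) losses <<- c(losses, ch)
      else recurse(ch)
    }
  }
  recurse(origin)
  list(presence = stats::setNames(pres, tree$tip.label), losses = losses)
}

.as_simulated_gene <- function(name, tree, origin, hist, resamples) {
  catalog <- catalog_from_tree(tree)
  structure(list(name = name,
                 origin = origin,
                 origin_label = .node_labels(tree, origin),
                 loss_branches = hist$losses,
                 loss_labels = .node_labels(tree, hist$losses),
                 profile = phylo_profile(name, hist$presence, catalog),
                 resamples = resamples),
            class = "simulated_gene")
}

#' @export
print.simulated_gene <- function(x, ...) {
  cat("Simulated gene", x$name, "- origin", x$origin_label, "with",
      length(x$loss_branches), "loss events",
      if (x$resamples > 0) sprintf("(%d resamples)", x$resamples) else "", "\n")
  invisible(x)
}

#' Simulate one gene's gain/loss history
#'
#' Places the gain according to the configured origin policy and descends
#' the tree, losing the gene on each branch with probability `loss_prob`
#' (loss is inherited: no events below a loss). A gene lost in all leaves
#' is, by default, resampled with an incremented seed — observed orthogroups
#' are conditioned on survival — with the resample count recorded; set
#' `resample_extinct = FALSE` to keep extinct genes (all-zero profile).
#'
#' @param tree `ape::phylo` from [simulate_species_tree()].
#' @param config A [simulation_config()].
#' @param gene_seed Integer seed for this gene.
#' @param name Gene label.
#' @param resample_extinct Resample extinct genes (default `TRUE`).
#' @param max_resample Retry bound before giving up.
#' @return Object of class `"simulated_gene"` with fields `name`, `origin`,
#'   `loss_branches` (node ids), `profile` ([phylo_profile()]) and
#'   `resamples`.
#' @export
simulate_gene_history <- function(tree, config, gene_seed,
                                  name = paste0("gene", gene_seed),
                                  resample_extinct = TRUE,
                                  max_resample = 100) {
  stopifnot(inherits(config, "simulation_config"), inherits(tree, "phylo"))
  attempt <- 0L
  repeat {
    res <- .with_seed(gene_seed + attempt, {
      origin <- .choose_origin(tree, config$origin_policy)
      list(origin = origin,
           hist = .draw_history(tree, origin, config$loss_prob))
    })
    if (any(res$hist$presence == 1L) || !resample_extinct) break
    attempt <- attempt + 1L
    if (attempt > max_resample)
      stop("gene extinct in all leaves after ", max_resample,
           " resampling attempts (loss_prob too high?)")
  }
  .as_simulated_gene(name, tree, res$origin, res$hist, attempt)
}

#' Simulate a co-evolving gene pair
#'
#' Both genes originate at the same node. Losses are drawn for gene A at
#' rate `loss_prob`; each A-loss is copied onto gene B with probability
#' `coupling`, and B additionally draws independent losses at rate
#' `loss_prob * (1 - coupling)`, so B's marginal loss rate stays close to
#' A's while the coupling dials the co-occurrence of their loss events.
#' With `coupling = 1` (and hence no residual rate) the profiles are
#' identical; with `coupling = 0` the histories are independent. Pairs with
#' either member extinct are jointly resampled.
#'
#' @param tree `ape::phylo` species tree.
#' @param config A [simulation_config()] (fields `loss_prob`, `coupling`,
#'   `origin_policy` are used).
#' @param pair_seed Integer seed for the pair.
#' @param names Labels of the two genes.
#' @param max_resample Retry bound.
#' @return List of two `"simulated_gene"` objects.
#' @export
simulate_coupled_pair <- function(tree, config, pair_seed,
                                  names = paste0("pair", pair_seed, c("A", "B")),
                                  max_resample = 100) {
  stopifnot(inherits(config, "simulation_config"), inherits(tree, "phylo"))
  attempt <- 0L
  repeat {
    res <- .with_seed(pair_seed + attempt, {
      origin <- .choose_origin(tree, config$origin_policy)
      a <- .draw_history(tree, origin, config$loss_prob)
      b <- .draw_coupled(tree, origin, a$losses, config$loss_prob,
                         config$coupling)
      list(origin = origin, a = a, b = b)
    })
    if ((any(res$a$presence == 1L) && any(res$b$presence == 1L))) break
    attempt <- attempt + 1L
    if (attempt > max_resample)
      stop("pair extinct after ", max_resample, " resampling attempts")
  }
  list(.as_simulated_gene(names[1], tree, res$origin, res$a, attempt),
       .as_simulated_gene(names[2], tree, res$origin, res$b, attempt))
}

#' Simulate a multifunctional triplet (enzyme retained iff a partner is)
#'
#' Simulates two (optionally coupled) partner genes and an enzyme whose
#' presence is the elementwise OR of the partners — the retention rule of a
#' multifunctional protein that is kept as long as at least one of its
#' interaction partners needs it — flipped per species with probability
#' `motif_noise`.
#'
#' @param tree `ape::phylo` species tree.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List with elements `enzyme` ([phylo_profile()]), `partnerA` and
#'   `partnerB` (`"simulated_gene"`).
#' @export
simulate_multifunctional_triplet <- function(tree, config, seed) {
  pair <- simulate_coupled_pair(tree, config, seed,
                                names = c("partnerA", "partnerB"))
  pa <- pair[[1]]$profile$presence
  pb <- pair[[2]]$profile$presence
  enz <- as.integer(pa | pb)
  if (config$motif_noise > 0) {
    enz <- .with_seed(seed + 7919L, {
      flip <- stats::runif(length(enz)) < config$motif_noise
      as.integer(ifelse(flip, 1L - enz, enz))
    })
  }
  catalog <- catalog_from_tree(tree)
  list(enzyme = phylo_profile("enzyme", enz, catalog),
       partnerA = pair[[1]], partnerB = pair[[2]])
}

# background alphabet for emitted sequences: the 20 amino acids minus the
# motif-defining residues K, R and P, so a planted motif is the only way a
# canonical/relaxed MIM can occur in a fixture sequence
.BACKGROUND_AA <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]
.PLANTED_MIM <- "KILSTDP"   # [RK][ILV](2) X(3) P instance
.MOTIF_OFFSET <- 50L        # 0-based plant position in emitted sequences

#' Write a simulated dataset to disk as analysis-ready fixtures
#'
#' Emits, for each simulated gene, an orthogroup FASTA file with one random
#' amino-acid sequence per present species (identifiers follow the 4-letter
#' code + 6-digit convention), plus the newick species tree, a ground-truth
#' TSV (origin, loss branches, profile string per gene) and a YAML echo of
#' the configuration. Background sequences are drawn from an alphabet
#' without K, R and P, so the only motif instances are planted ones: for a
#' gene named in `motif_partners`, a canonical MIM is inserted at a fixed
#' offset in the sequences of exactly those species where the designated
#' partner gene is present (each species' call flipped with probability
#' `motif_noise`). Output is byte-identical given the same inputs and seed.
#'
#' @param genes Named list of `"simulated_gene"` objects (names = gene
#'   labels; defaults to their `$name` fields).
#' @param tree The `ape::phylo` species tree the genes were simulated on.
#' @param config The [simulation_config()] used.
#' @param outdir Output directory (created if needed).
#' @param motif_partners Optional named character vector mapping a
#'   motif-carrier gene name to its partner gene name.
#' @return Invisibly, a list with the emitted file paths and the per-carrier
#'   true motif profiles.
#' @export
emit_fixture_dataset <- function(genes, tree, config, outdir,
                                 motif_partners = NULL) {
  stopifnot(inherits(config, "simulation_config"), inherits(tree, "phylo"))
  if (is.null(names(genes)))
    names(genes) <- vapply(genes, function(g) g$name, character(1))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  if (!is.null(motif_partners)) {
    missing <- setdiff(c(names(motif_partners), motif_partners), names(genes))
    if (length(missing) > 0)
      stop("motif_partners refers to unknown genes: ",
           paste(missing, collapse = ", "))
  }

  tree_path <- file.path(outdir, "tree.nwk")
  ape::write.tree(tree, tree_path)
  yaml_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(config), yaml_path)

  truth <- data.frame(
    gene = names(genes),
    origin = vapply(genes, function(g) g$origin_label, character(1)),
    losses = vapply(genes, function(g)
      paste(g$loss_labels, collapse = ","), character(1)),
    profile = vapply(genes, function(g)
      paste(g$profile$presence, collapse = ""), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  motif_truth <- list()
  fasta_paths <- character(0)
  .with_seed(config$seed, {
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      gname <- names(genes)[gi]
      pres <- g$profile$presence
      plant <- NULL
      if (!is.null(motif_partners) && gname %in% names(motif_partners)) {
        partner <- genes[[motif_partners[[gname]]]]$profile$presence
        plant <- as.integer(pres & partner)
        if (config$motif_noise > 0) {
          flip <- stats::runif(length(plant)) < config$motif_noise
          plant <- as.integer(ifelse(flip & pres == 1L, 1L - plant, plant))
        }
        names(plant) <- names(pres)
        motif_truth[[gname]] <- plant
      }
      lines <- character(0)
      for (sp in names(pres)[pres == 1L]) {
        seqchars <- sample(.BACKGROUND_AA, config$sequence_length,
                           replace = TRUE)
        if (!is.null(plant) && plant[[sp]] == 1L) {
          mim <- strsplit(.PLANTED_MIM, "")[[1]]
          seqchars[.MOTIF_OFFSET + seq_along(mim)] <- mim
        }
        id <- sprintf("%s%06d", sp, gi)
        lines <- c(lines, paste0(">", id), paste(seqchars, collapse = ""))
      }
      fp <- file.path(outdir, paste0(gname, ".fasta"))
      writeLines(lines, fp)
      fasta_paths <- c(fasta_paths, fp)
    }
  })
  invisible(list(tree = tree_path, truth = truth_path, config = yaml_path,
                 fasta = fasta_paths, motif_truth = motif_truth))
}
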