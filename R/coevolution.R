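#' Pearson correlation between two binary phylogenetic profiles
#'
#' On binary vectors the Pearson coefficient equals the phi coefficient of
#' the 2x2 co-occurrence table, so it measures how often two genes co-occur
#' across genomes relative to their marginal frequencies. Pearson is
#' undefined for a constant profile (all present or all absent): by
#' convention the function returns 0 there and marks the result with a
#' `"constant"` attribute, so non-informative profiles stay in a correlation
#' matrix (for clustering) without ever crossing an interaction threshold.
#'
#' @param a,b Binary vectors of equal length >= 2, or [phylo_profile()]
#'   objects (their presence vectors are used).
#' @return The correlation as a single numeric; attribute `constant` is
#'   `TRUE` when either input was constant (value then 0).
#' @examples
#' profile_pearson(c(1, 1, 0, 0), c(1, 0, 1, 0))  # phi of a balanced table
#' @export
profile_pearson <- function(a, b) {
  a <- .as_presence(a); b <- .as_presence(b)
  if (length(a) != length(b))
    stop("profile length mismatch: ", length(a), " vs ", length(b))
  if (length(a) < 2) stop("profiles must have length >= 2")
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("profiles must be binary (0/1)")
  const <- length(unique(a)) < 2 || length(unique(b)) < 2
  if (const) return(structure(0, constant = TRUE))
  n <- length(a)
  sa <- sum(a); sb <- sum(b); sab <- sum(a * b)
  r <- (n * sab - sa * sb) /
    sqrt(as.numeric(sa) * (n - sa) * sb * (n - sb))
  structure(as.numeric(r), constant = FALSE)
}

.as_presence <- function(x) {
  if (inherits(x, "phylo_profile")) return(as.numeric(x$presence))
  if (inherits(x, "motif_profile")) return(as.numeric(x$presence))
  as.numeric(x)
}

#' All-pairs profile correlation matrix
#'
#' Scores every unordered pair of profiles with [profile_pearson()].
#' Constant profiles are flagged; their rows/columns are 0 (including the
#' diagonal), and calibration sweeps ignore pairs that involve them.
#'
#' @param profiles List of >= 2 [phylo_profile()] sharing one catalog.
#' @return Object of class `"coev_cor"`: list with `proteins`, symmetric
#'   matrix `r` (unit diagonal for non-constant profiles) and logical
#'   `constant` flags.
#' @export
correlation_matrix <- function(profiles) {
  .check_shared_catalog(profiles)
  if (length(profiles) < 2) stop("need at least 2 profiles")
  prot <- vapply(profiles, function(p) p$protein_name, character(1))
  if (anyDuplicated(prot)) stop("duplicated protein names among profiles")
  pres <- lapply(profiles, .as_presence)
  n <- length(pres)
  constant <- vapply(pres, function(v) length(unique(v)) < 2, logical(1))
  r <- matrix(0, n, n, dimnames = list(prot, prot))
  for (i in seq_len(n)) {
    if (!constant[i]) r[i, i] <- 1
    if (i < n) for (j in (i + 1L):n) {
      rij <- profile_pearson(pres[[i]], pres[[j]])
      r[i, j] <- r[j, i] <- as.numeric(rij)
    }
  }
  structure(list(proteins = prot, r = r,
                 constant = stats::setNames(constant, prot)),
            class = "coev_cor")
}

#' @export
print.coev_cor <- function(x, ...) {
  cat("Profile correlation matrix:", length(x$proteins), "proteins",
      sprintf("(%d constant)\n", sum(x$constant)))
  rr <- x$r[upper.tri(x$r)]
  if (length(rr)) cat(sprintf("  r range [%.3f, %.3f]\n", min(rr), max(rr)))
  invisible(x)
}

#' Joint (combined) phylogenetic profile
#'
#' The joint profile of a set of genes is present wherever at least one of
#' them is present (elementwise OR), with summed copy numbers. A
#' multifunctional protein retained whenever at least one of its interaction
#' partners is present is expected to correlate better with the partners'
#' joint profile than with either partner alone.
#'
#' @param components List of >= 1 [phylo_profile()] sharing one catalog
#'   (>= 2 for a non-trivial join).
#' @param name Protein label for the joint profile.
#' @return A [phylo_profile()].
#' @export
joint_profile <- function(components, name) {
  if (length(components) == 0) stop("empty component list")
  codes <- .check_shared_catalog(components)
  cn <- Reduce(`+`, lapply(components, function(p) p$copy_number))
  phylo_profile(name, as.integer(cn), species_catalog(codes))
}

#' Read an interaction reference (pair list) from TSV
#'
#' Two columns, one established interacting protein pair per row.
#' @param path Path to a two-column TSV (no header by default).
#' @param header Whether the file has a header row.
#' @return Two-column character matrix of unordered pairs.
#' @export
read_interaction_pairs <- function(path, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("interaction reference must have two columns")
  as.matrix(df[, 1:2])
}

#' Calibrate an interaction threshold by enrichment sweep
#'
#' Sweeps candidate thresholds over the distinct observed correlation values
#' and, for each candidate `t`, computes the enrichment of established
#' interacting pairs among pairs with `r >= t` relative to their base rate
#' among all pairs. The returned threshold is the smallest candidate
#' achieving at least the requested fold enrichment (the convention used to
#' define "likely interacting" pairs); if no candidate achieves it the
#' sentinel `-1` is returned. Pairs involving constant profiles are excluded
#' from the sweep.
#'
#' @param cm A [correlation_matrix()] result.
#' @param ref Two-column matrix/data.frame of unordered reference pairs, or a
#'   list of length-2 character vectors; labels must be among the profiled
#'   proteins, no self-pairs.
#' @param fold Required fold enrichment (> 0), default 6.
#' @return Object of class `"coev_calibration"`: `threshold` (`-1` if
#'   unattainable), `fold` (achieved at the threshold, `NA` for sentinel),
#'   `base_rate`, and the full `sweep` data frame (threshold, n_selected,
#'   n_ref_selected, enrichment).
#' @export
calibrate_threshold <- function(cm, ref, fold = 6) {
  stopifnot(inherits(cm, "coev_cor"))
  if (!is.numeric(fold) || length(fold) != 1 || fold <= 0)
    stop("`fold` must be a positive number")
  ref <- .as_pair_matrix(ref)
  if (nrow(ref) == 0) stop("empty interaction reference")
  if (any(ref[, 1] == ref[, 2])) stop("self-pairs in interaction reference")
  unknown <- setdiff(c(ref), cm$proteins)
  if (length(unknown) > 0)
    stop("reference proteins not in the correlation matrix: ",
         paste(unique(unknown), collapse = ", "))

  keep <- cm$proteins[!cm$constant]
  if (length(keep) < 2) stop("fewer than two non-constant profiles")
  idx <- utils::combn(keep, 2)
  pair_key <- apply(idx, 2, function(p) paste(sort(p), collapse = "\r"))
  pair_r <- cm$r[cbind(idx[1, ], idx[2, ])]
  ref_key <- unique(apply(ref, 1, function(p) paste(sort(p), collapse = "\r")))
  is_ref <- pair_key %in% ref_key
  base_rate <- mean(is_ref)
  if (base_rate == 0) stop("no reference pair among the profiled pairs")

  cand <- sort(unique(pair_r))
  sweep <- data.frame(threshold = cand,
                      n_selected = NA_integer_, n_ref_selected = NA_integer_,
                      enrichment = NA_real_)
  for (i in seq_along(cand)) {
    sel <- pair_r >= cand[i]
    sweep$n_selected[i] <- sum(sel)
    sweep$n_ref_selected[i] <- sum(is_ref & sel)
    sweep$enrichment[i] <- (sum(is_ref & sel) / sum(sel)) / base_rate
  }
  hit <- which(sweep$enrichment >= fold)
  threshold <- if (length(hit) > 0) cand[min(hit)] else -1
  structure(list(threshold = threshold,
                 fold = if (length(hit) > 0) sweep$enrichment[min(hit)] else NA_real_,
                 requested_fold = fold,
                 base_rate = base_rate,
                 sweep = sweep),
            class = "coev_calibration")
}

.as_pair_matrix <- function(ref) {
  if (is.list(ref) && !is.data.frame(ref))
    ref <- do.call(rbind, lapply(ref, function(p) as.character(p[1:2])))
  ref <- as.matrix(ref)
  if (ncol(ref) != 2) stop("reference pairs must have two columns")
  storage.mode(ref) <- "character"
  ref
}

#' @export
print.coev_calibration <- function(x, ...) {
  if (x$threshold == -1) {
    cat(sprintf("Calibration: %g-fold enrichment unattainable (max %.2f)\n",
                x$requested_fold, max(x$sweep$enrichment)))
  } else {
    cat(sprintf("Calibration: threshold r = %.4g (%.2f-fold vs base rate %.4g)\n",
                x$threshold, x$fold, x$base_rate))
  }
  invisible(x)
}

#' Average-linkage clustering of phylogenetic profiles
#'
#' Converts correlations into distances `d = 1 - r` and clusters the
#' proteins by average linkage (UPGMA-style agglomeration). Proteins are
#' ordered lexicographically before clustering so that ties are broken
#' deterministically across platforms.
#'
#' @param cm A [correlation_matrix()] result.
#' @return A `stats::hclust` object (merge history and non-decreasing
#'   heights in distance units).
#' @export
cluster_profiles <- function(cm) {
  stopifnot(inherits(cm, "coev_cor"))
  if (length(cm$proteins) < 2) stop("need >= 2 proteins to cluster")
  ord <- order(cm$proteins)
  d <- 1 - cm$r[ord, ord]
  if (any(!is.finite(d))) stop("non-finite distances in profile matrix")
  diag(d) <- 0
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Phylogenetic profiles of reference protein families
#'
#' Builds one binary profile per reference (sub)family from a protein-to-
#' family assignment table (e.g. PANTHER-style output): a family is present
#' in a species when at least one of that species' proteins is assigned to
#' it. Subfamily identifiers of the form `FAMILY:SFn` also propagate their
#' members to the parent `FAMILY` profile.
#'
#' @param assignments Data frame (or TSV path) with columns `seq_id` and
#'   `family` (first two columns are used).
#' @param catalog A [species_catalog()].
#' @param strict Unknown species codes abort (`TRUE`) or are skipped with a
#'   warning.
#' @return Binary integer matrix, rows = family ids, columns = species codes.
#' @export
family_profiles <- function(assignments, catalog, strict = TRUE) {
  stopifnot(inherits(catalog, "species_catalog"))
  if (is.character(assignments) && length(assignments) == 1)
    assignments <- utils::read.table(assignments, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
  if (ncol(assignments) < 2)
    stop("assignment table needs columns: seq_id, family")
  seq_id <- as.character(assignments[[1]])
  fam <- as.character(assignments[[2]])
  code <- parse_species_code(seq_id)
  unknown <- setdiff(code, catalog$codes)
  if (length(unknown) > 0) {
    msg <- paste("assignment table has species not in the catalog:",
                 paste(unknown, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, " (skipped)")
    keep <- code %in% catalog$codes
    code <- code[keep]; fam <- fam[keep]
  }
  # subfamily hits also count for the parent family
  is_sub <- grepl(":", fam, fixed = TRUE)
  code <- c(code, code[is_sub])
  fam <- c(fam, sub(":.*$", "", fam[is_sub]))
  fams <- sort(unique(fam))
  m <- matrix(0L, length(fams), length(catalog$codes),
              dimnames = list(fams, catalog$codes))
  m[cbind(match(fam, fams), match(code, catalog$codes))] <- 1L
  m
}

#' Best-matching reference families for a query profile
#'
#' Ranks all reference family profiles by their correlation with the query
#' profile (descending; ties broken by lexicographic family id) and returns
#' the top `k` — the screen used to nominate unannotated families that
#' co-evolve with a protein of interest.
#'
#' @param query A [phylo_profile()] (or binary vector over the same catalog).
#' @param families Binary matrix as returned by [family_profiles()].
#' @param k Number of matches to return (default 30); if larger than the
#'   number of families, all are returned.
#' @return Data frame with columns `family` and `r`, ranked.
#' @export
family_top_matches <- function(query, families, k = 30) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("`k` must be positive")
  if (is.null(dim(families)) || nrow(families) == 0)
    stop("`families` must be a non-empty family-by-species matrix")
  q <- .as_presence(query)
  r <- apply(families, 1, function(f) as.numeric(profile_pearson(q, f)))
  ord <- order(-r, rownames(families))
  top <- utils::head(ord, k)
  data.frame(family = rownames(families)[top], r = r[top],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Families recurring across many top-match lists
#'
#' Given the per-query ranked family lists, tallies in how many lists each
#' family appears and reports those appearing at least `min_count` times —
#' recurrent families are candidates for a shared function with the queried
#' protein set.
#'
#' @param toplists Named list: one [family_top_matches()] data frame (or
#'   character vector of family ids) per query protein.
#' @param min_count Minimum number of lists a family must appear in (>= 1).
#' @return Data frame with columns `family`, `count`, sorted by decreasing
#'   count (ties by family id).
#' @export
recurrent_families <- function(toplists, min_count) {
  if (length(toplists) == 0) stop("`toplists` must be non-empty")
  if (!is.numeric(min_count) || min_count < 1) stop("`min_count` must be >= 1")
  fams <- lapply(toplists, function(x)
    unique(if (is.data.frame(x)) as.character(x$family) else as.character(x)))
  tab <- table(unlist(fams))
  tab <- tab[tab >= min_count]
  out <- data.frame(family = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
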