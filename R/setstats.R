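# Conservation statistics for protein sets (e.g. a whole machine such as the
# kinetochore versus the APC/C): occurrence frequencies, profile entropies,
# anchor-conditioned completeness, loss-frequency comparisons and the
# correlation between loss frequency and sequence evolution rate.

#' Occurrence frequency of a profile
#'
#' Fraction of catalog species in which the protein is present.
#' @param profile A [phylo_profile()] or binary vector.
#' @return Numeric in `[0, 1]`.
#' @export
occurrence_frequency <- function(profile) {
  p <- .as_presence(profile)
  if (length(p) == 0) stop("empty profile")
  mean(p)
}

#' Binary entropy of a profile
#'
#' Shannon entropy (in bits) of the presence fraction `p`:
#' `-p log2 p - (1-p) log2(1-p)`, with the convention `0 log 0 = 0`. A
#' protein present in half of the species is maximally "diverse" (1 bit);
#' ubiquitous or absent proteins score 0.
#'
#' @param profile A [phylo_profile()] or binary vector.
#' @return Entropy in bits.
#' @examples
#' profile_entropy(c(1, 1, 0, 0))  # 1 bit
#' @export
profile_entropy <- function(profile) {
  p <- occurrence_frequency(profile)
  h <- function(q) if (q <= 0 || q >= 1) 0 else -q * log2(q)
  h(p) + h(1 - p)
}

#' Define a protein set with anchor proteins
#'
#' Anchors are the proteins whose joint presence marks a species as "having
#' the machine" at all (e.g. the DNA-binding and microtubule-binding ends of
#' the kinetochore); completeness is only meaningful in such species.
#'
#' @param name Set label.
#' @param members Character vector of member protein labels (non-empty).
#' @param anchors Character vector of anchor protein labels.
#' @return Object of class `"protein_set"`.
#' @export
protein_set <- function(name, members, anchors = character(0)) {
  if (length(members) == 0) stop("`members` must be non-empty")
  structure(list(name = name, members = unique(as.character(members)),
                 anchors = unique(as.character(anchors))),
            class = "protein_set")
}

#' Anchor-conditioned completeness of a protein set
#'
#' Restricts to species in which all anchor proteins are present and reports,
#' per such species, the fraction of set members present, plus the mean. For
#' comparison the unconditional mean over all catalog species is reported as
#' well (`mean_all_species`), since the two conventions give different
#' headline numbers.
#'
#' @param profiles Named list of [phylo_profile()] covering the members and
#'   anchors.
#' @param setdef A [protein_set()].
#' @return Object of class `"set_completeness"`: `per_species` (named
#'   fractions over passing species), `mean`, `mean_all_species`,
#'   `n_species_passing`.
#' @export
conditional_completeness <- function(profiles, setdef) {
  stopifnot(inherits(setdef, "protein_set"))
  need <- unique(c(setdef$members, setdef$anchors))
  missing <- setdiff(need, names(profiles))
  if (length(missing) > 0)
    stop("profiles missing for: ", paste(missing, collapse = ", "))
  codes <- .check_shared_catalog(profiles[need])
  pres <- profile_matrix(profiles[need], "presence")
  pass <- rep(TRUE, length(codes))
  for (a in setdef$anchors) pass <- pass & pres[a, ] == 1L
  if (!any(pass))
    stop("no species carries all anchors (",
         paste(setdef$anchors, collapse = ", "), ")")
  member_frac <- colMeans(pres[setdef$members, , drop = FALSE])
  names(member_frac) <- codes
  structure(list(set = setdef$name,
                 per_species = member_frac[pass],
                 mean = mean(member_frac[pass]),
                 mean_all_species = mean(member_frac),
                 n_species_passing = sum(pass)),
            class = "set_completeness")
}

#' @export
print.set_completeness <- function(x, ...) {
  cat(sprintf("Set '%s': mean completeness %.1f%% over %d anchor-positive species",
              x$set, 100 * x$mean, x$n_species_passing),
      sprintf("(%.1f%% over all species)\n", 100 * x$mean_all_species))
  invisible(x)
}

#' Compare loss frequencies between two protein sets
#'
#' Two-sided Mann-Whitney rank test on the per-protein Dollo loss counts of
#' two sets, reported with the sample means. For small samples (total
#' n <= `exact_limit`) the p-value is computed by exact enumeration of all
#' rank assignments (midranks for ties; two-sided p = twice the smaller
#' tail, capped at 1); larger samples use the normal approximation of
#' [stats::wilcox.test()].
#'
#' @param lossesA,lossesB Numeric vectors of loss counts (each >= 2 values).
#' @param exact_limit Largest total sample size for exact enumeration.
#' @return List: `statistic` (rank-sum W of sample A), `p_value`, `means`
#'   (length 2), `method`.
#' @export
compare_loss_frequencies <- function(lossesA, lossesB, exact_limit = 20) {
  if (length(lossesA) < 2 || length(lossesB) < 2)
    stop("both samples need >= 2 values")
  na <- length(lossesA); nb <- length(lossesB); n <- na + nb
  rk <- rank(c(lossesA, lossesB))
  W <- sum(rk[seq_len(na)])
  if (n <= exact_limit && choose(n, na) <= 2e5) {
    sums <- utils::combn(rk, na, sum)
    p_lo <- mean(sums <= W + 1e-9)
    p_hi <- mean(sums >= W - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact permutation rank-sum"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(lossesA, lossesB, exact = FALSE)$p.value)
    method <- "Mann-Whitney (normal approximation)"
  }
  list(statistic = W, p_value = p,
       means = c(mean(lossesA), mean(lossesB)), method = method)
}

#' Read a per-protein evolutionary-rate table
#'
#' @param path TSV with header columns `protein`, `dnds`, `pct_id` (for a
#'   stated species pair, e.g. human--mouse).
#' @return Data frame with those columns.
#' @export
read_rate_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("protein", "dnds", "pct_id")
  if (!all(need %in% names(df)))
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  if (any(df$dnds < 0)) stop("dN/dS values must be >= 0")
  if (any(df$pct_id < 0 | df$pct_id > 100))
    stop("percent identity must be in [0, 100]")
  df
}

#' Correlate loss frequency with sequence evolution rate
#'
#' Spearman rank correlation (averaged ranks for ties) between per-protein
#' Dollo loss counts and an evolutionary-rate measure, over the proteins
#' present in both tables. Positive correlation with dN/dS suggests a
#' common cause behind frequent loss and fast sequence evolution.
#'
#' @param losses Named numeric vector: protein -> loss count.
#' @param rates Rate table as from [read_rate_table()].
#' @param field `"dnds"` or `"pct_id"`.
#' @return List: `rho`, `p_value`, `n` (shared proteins).
#' @export
correlate_loss_vs_rate <- function(losses, rates, field = c("dnds", "pct_id")) {
  field <- match.arg(field)
  shared <- intersect(names(losses), rates$protein)
  if (length(shared) < 3)
    stop("need >= 3 proteins shared between losses and rate table")
  x <- as.numeric(losses[shared])
  y <- rates[[field]][match(shared, rates$protein)]
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(shared))
}

#' Copy-number summary across a profile set
#'
#' Stacks the per-protein copy-number vectors and flags proteins with any
#' species at copy number >= 2 — candidates for lineage-specific duplication
#' and subfunctionalization.
#'
#' @param profiles List of [phylo_profile()] sharing one catalog.
#' @return List: `matrix` (protein x species copy numbers) and `summary`
#'   data frame (protein, max_copies, mean_copies, multi_copy flag).
#' @export
copy_number_summary <- function(profiles) {
  m <- profile_matrix(profiles, "copy_number")
  list(matrix = m,
       summary = data.frame(
         protein = rownames(m),
         max_copies = apply(m, 1, max),
         mean_copies = rowMeans(m),
         multi_copy = apply(m, 1, function(v) any(v >= 2L)),
         row.names = NULL, stringsAsFactors = FALSE))
}
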