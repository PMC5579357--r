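# Short-linear-motif scanning and motif/partner co-occurrence statistics.
#
# The motif of interest is the Mad2-interacting motif (MIM) carried by Mad1
# and Cdc20 orthologs. Its canonical form is a positive residue, two
# hydrophobic residues, a bounded spacer and a proline:
#   [RK][ILV](2)X(3,7)P
# The relaxed form additionally admits land-plant-style variants:
#   [ILV](2)X(3,7)P  or  [RK][ILV](2)
# Patterns are compiled from this bracket notation into a small list of
# alternative branches, each a sequence of residue classes, single
# wildcards, and one bounded gap; gaps are matched lazily (shortest first).

.CANONICAL_MIM <- "[RK][ILV](2)X(3,7)P"
.RELAXED_MIM <- "[ILV](2)X(3,7)P|[RK][ILV](2)"

#' Compile a sequence motif pattern
#'
#' Compiles a motif definition written in bracket notation into a scanning
#' pattern. The grammar: `[ABC]` is a residue class, optionally followed by
#' a repeat count `(n)`; `X` is a single arbitrary residue; `X(n,m)` is a
#' bounded gap of n--m arbitrary residues; a bare letter matches itself; `|`
#' separates alternative branches. A pattern `X` (wildcard or gap position)
#' matches any residue character including the ambiguity letter `X`, but
#' never a stop (`*`) or gap (`-`) character; residue classes match their
#' listed letters only.
#'
#' @param name `"canonical_MIM"`, `"relaxed_MIM"`, or a custom label (then
#'   `definition` is required).
#' @param definition Pattern string; defaults to the built-in definition for
#'   the two named MIM patterns.
#' @return Object of class `"motif_pattern"`.
#' @examples
#' motif_pattern("canonical_MIM")
#' motif_pattern("custom", "[DE]X(1,3)[FY]")
#' @export
motif_pattern <- function(name = c("canonical_MIM", "relaxed_MIM"),
                          definition = NULL) {
  if (is.null(definition)) {
    name <- match.arg(name)
    definition <- switch(name,
                         canonical_MIM = .CANONICAL_MIM,
                         relaxed_MIM = .RELAXED_MIM)
  } else {
    stopifnot(is.character(name), length(name) == 1)
  }
  branches <- lapply(strsplit(definition, "|", fixed = TRUE)[[1]],
                     .parse_motif_branch)
  min_len <- vapply(branches, function(b)
    sum(vapply(b, function(e) if (e$type == "gap") e$min else 1L, integer(1))),
    integer(1))
  max_len <- vapply(branches, function(b)
    sum(vapply(b, function(e) if (e$type == "gap") e$max else 1L, integer(1))),
    integer(1))
  structure(list(name = name, definition = definition, branches = branches,
                 min_len = min(min_len), max_len = max(max_len)),
            class = "motif_pattern")
}

.parse_motif_branch <- function(txt) {
  txt <- gsub("[[:space:]]+", "", txt)
  if (!nzchar(txt)) stop("empty motif branch")
  elems <- list()
  i <- 1L
  n <- nchar(txt)
  take_count <- function(i) {
    # returns list(counts c(min,max), next index); NULL if no '(' at i
    if (i > n || substr(txt, i, i) != "(") return(NULL)
    close <- regexpr(")", substr(txt, i, n), fixed = TRUE)
    if (close < 0) stop("unbalanced '(' in motif definition: ", txt)
    inner <- substr(txt, i + 1L, i + close - 2L)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    cnt <- suppressWarnings(as.integer(parts))
    if (any(is.na(cnt)) || length(cnt) < 1 || length(cnt) > 2)
      stop("bad repeat count '(", inner, ")' in motif definition")
    if (length(cnt) == 1) cnt <- c(cnt, cnt)
    if (cnt[1] > cnt[2] || cnt[1] < 0)
      stop("bad repeat range '(", inner, ")' in motif definition")
    list(count = cnt, nxt = i + close)
  }
  while (i <= n) {
    ch <- substr(txt, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(txt, i, n), fixed = TRUE)
      if (close < 0) stop("unbalanced '[' in motif definition: ", txt)
      chars <- strsplit(toupper(substr(txt, i + 1L, i + close - 2L)), "")[[1]]
      if (length(chars) == 0) stop("empty residue class in: ", txt)
      i <- i + close
      cnt <- take_count(i)
      reps <- 1L
      if (!is.null(cnt)) {
        if (cnt$count[1] != cnt$count[2])
          stop("residue classes take a fixed repeat count only")
        reps <- cnt$count[1]; i <- cnt$nxt
      }
      for (k in seq_len(reps))
        elems[[length(elems) + 1L]] <- list(type = "class", chars = chars)
    } else if (toupper(ch) == "X") {
      i <- i + 1L
      cnt <- take_count(i)
      if (is.null(cnt)) {
        elems[[length(elems) + 1L]] <- list(type = "gap", min = 1L, max = 1L)
      } else {
        elems[[length(elems) + 1L]] <-
          list(type = "gap", min = cnt$count[1], max = cnt$count[2])
        i <- cnt$nxt
      }
    } else if (grepl("^[A-Za-z]$", ch)) {
      i <- i + 1L
      cnt <- take_count(i)
      reps <- 1L
      if (!is.null(cnt)) {
        if (cnt$count[1] != cnt$count[2])
          stop("literal residues take a fixed repeat count only")
        reps <- cnt$count[1]; i <- cnt$nxt
      }
      for (k in seq_len(reps))
        elems[[length(elems) + 1L]] <- list(type = "class", chars = toupper(ch))
    } else {
      stop("unexpected character '", ch, "' in motif definition: ", txt)
    }
  }
  elems
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("Motif pattern", x$name, ":", x$definition,
      sprintf("(match length %d-%d)\n", x$min_len, x$max_len))
  invisible(x)
}

# shortest match of a branch starting at position `pos` (1-based) in the
# character vector `chars`; returns end position (inclusive) or NA
.match_branch_at <- function(chars, pos, elems, ei = 1L) {
  if (ei > length(elems)) return(pos - 1L)
  e <- elems[[ei]]
  n <- length(chars)
  if (e$type == "class") {
    if (pos > n || !(chars[pos] %in% e$chars)) return(NA_integer_)
    return(.match_branch_at(chars, pos + 1L, elems, ei + 1L))
  }
  # gap: lazily try the shortest span first; wildcard residues exclude
  # stop codons and alignment gap characters
  for (g in e$min:e$max) {
    span <- if (g > 0) chars[pos + seq_len(g) - 1L] else character(0)
    if (pos + g - 1L > n) break
    if (g > 0 && any(span %in% c("*", "-", ".") | is.na(span))) break
    end <- .match_branch_at(chars, pos + g, elems, ei + 1L)
    if (!is.na(end)) return(end)
  }
  NA_integer_
}

#' Find all motif occurrences in a sequence
#'
#' Scans every start position with every branch of the pattern, reporting
#' the shortest (lazy) match per start position and branch. Overlapping
#' matches are allowed; identical (start, end) duplicates across branches
#' are collapsed. Coordinates are 0-based, half-open.
#'
#' @param sequence Single amino-acid string (case-insensitive).
#' @param pattern A [motif_pattern()].
#' @return Data frame with columns `start`, `end` (0-based half-open) and
#'   `match`; zero rows when the motif is absent.
#' @examples
#' find_motif_occurrences("MRILAAAPK", motif_pattern("canonical_MIM"))
#' @export
find_motif_occurrences <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("`sequence` must be a single non-empty string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  starts <- integer(0); ends <- integer(0)
  for (pos in seq_len(max(0L, n - pattern$min_len + 1L))) {
    for (b in pattern$branches) {
      end <- .match_branch_at(chars, pos, b)
      if (!is.na(end) && end >= pos) {
        starts <- c(starts, pos); ends <- c(ends, end)
      }
    }
  }
  if (length(starts) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  keep <- !duplicated(cbind(starts, ends))
  starts <- starts[keep]; ends <- ends[keep]
  ord <- order(starts, ends)
  data.frame(start = starts[ord] - 1L, end = ends[ord],
             match = vapply(ord, function(i)
               paste(chars[starts[i]:ends[i]], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

#' Read an aligned FASTA file (equal-width sequences)
#'
#' @param path Aligned FASTA file path.
#' @return Named character vector of aligned sequences (ids = first header
#'   token); unequal widths are an error.
#' @export
read_alignment_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty alignment file: ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (length(unique(Biostrings::width(aa))) != 1)
    stop("ragged alignment: sequences have unequal aligned lengths")
  stats::setNames(as.character(aa), ids)
}

#' Scan a conserved alignment window for a motif
#'
#' Motif presence is assessed at the conserved position established by an
#' anchor sequence: the alignment columns occupied by the anchor's motif,
#' widened by `slack` columns on each side, are extracted for every
#' sequence, gap characters are stripped, and the window is scanned with the
#' pattern. A species is scored motif-present when any of its sequences has
#' a hit inside the window; a motif elsewhere in the protein does not count.
#'
#' @param msa Named character vector of equal-length aligned sequences (ids
#'   follow the 4-letter-code + 6-digit convention), or a path readable by
#'   [read_alignment_fasta()].
#' @param pattern A [motif_pattern()].
#' @param anchor_id Identifier of the anchor sequence (must carry the motif).
#' @param catalog A [species_catalog()] defining the output profile order.
#' @param slack Window widening in alignment columns (default 5).
#' @param anchor_start,anchor_end Optional 0-based half-open residue
#'   coordinates of the anchor motif (defaults to its first motif hit).
#' @return Object of class `"motif_profile"`: `protein_name` (motif +
#'   anchor), `motif`, `codes`, binary `presence` over the catalog, and
#'   `n_scanned` species with sequence.
#' @export
scan_alignment_window <- function(msa, pattern, anchor_id, catalog,
                                  slack = 5, anchor_start = NULL,
                                  anchor_end = NULL) {
  stopifnot(inherits(pattern, "motif_pattern"),
            inherits(catalog, "species_catalog"))
  if (is.character(msa) && length(msa) == 1 && file.exists(msa))
    msa <- read_alignment_fasta(msa)
  if (is.null(names(msa)) || any(!nzchar(names(msa))))
    stop("alignment sequences must be named by sequence id")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: sequences have unequal aligned lengths")
  if (!anchor_id %in% names(msa))
    stop("anchor sequence '", anchor_id, "' not in the alignment")
  if (!is.numeric(slack) || slack < 0) stop("`slack` must be >= 0")

  gap_chars <- c("-", ".")
  anchars <- strsplit(toupper(msa[[anchor_id]]), "")[[1]]
  res_cols <- which(!(anchars %in% gap_chars))
  degapped <- paste(anchars[res_cols], collapse = "")
  if (is.null(anchor_start) || is.null(anchor_end)) {
    hits <- find_motif_occurrences(degapped, pattern)
    if (nrow(hits) == 0)
      stop("anchor sequence '", anchor_id, "' carries no '", pattern$name,
           "' motif")
    anchor_start <- hits$start[1]; anchor_end <- hits$end[1]
  }
  if (anchor_end <= anchor_start || anchor_end > length(res_cols))
    stop("invalid anchor motif coordinates")
  motif_cols <- res_cols[(anchor_start + 1L):anchor_end]
  window <- max(1L, min(motif_cols) - as.integer(slack)):
    min(length(anchars), max(motif_cols) + as.integer(slack))

  codes <- parse_species_code(names(msa))
  unknown <- setdiff(codes, catalog$codes)
  if (length(unknown) > 0)
    stop("alignment has species not in the catalog: ",
         paste(unknown, collapse = ", "))
  presence <- stats::setNames(integer(length(catalog$codes)), catalog$codes)
  for (i in seq_along(msa)) {
    w <- strsplit(toupper(msa[[i]]), "")[[1]][window]
    sub <- paste(w[!(w %in% gap_chars)], collapse = "")
    hit <- nzchar(sub) && nrow(find_motif_occurrences(sub, pattern)) > 0
    if (hit) presence[codes[i]] <- 1L
  }
  structure(list(protein_name = paste0(pattern$name, "@", anchor_id),
                 motif = pattern$name,
                 codes = catalog$codes,
                 presence = presence,
                 n_scanned = length(unique(codes))),
            class = "motif_profile")
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("Motif profile", x$protein_name, "- present in", sum(x$presence), "of",
      length(x$codes), "species\n")
  invisible(x)
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` species from a
#' universe of `N` of which `K` carry the partner, the probability of seeing
#' at least `k` carriers. This is the one-sided over-representation test
#' used for motif/partner co-occurrence.
#'
#' @param N Universe size.
#' @param K Number of "successes" in the universe.
#' @param n Draw size.
#' @param k Observed successes in the draw.
#' @return Probability in `[0, 1]`.
#' @examples
#' hypergeom_tail(10, 5, 5, 5)  # 1/252
#' @export
hypergeom_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals != round(vals)) || any(vals < 0))
    stop("N, K, n, k must be non-negative integers")
  if (K > N || n > N) stop("inconsistent counts: need K <= N and n <= N")
  if (k > min(K, n)) stop("inconsistent counts: need k <= min(K, n)")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Motif/partner co-occurrence table and test
#'
#' Restricts the universe to species carrying the motif's host protein (no
#' ortholog, no chance of a motif), cross-tabulates partner presence against
#' motif presence there, and reports the one-sided hypergeometric
#' over-representation p-value together with the Pearson/phi correlation of
#' the two restricted profiles.
#'
#' @param motif A `motif_profile` (or [phylo_profile()]) of motif presence.
#' @param partner [phylo_profile()] of the interaction partner.
#' @param carrier [phylo_profile()] of the motif's host protein.
#' @return Object of class `"cooccurrence"`: `N` (carrier-present species),
#'   `K` (partner present), `n` (motif present), `k` (both), `p_value`, `r`.
#' @export
motif_partner_cooccurrence <- function(motif, partner, carrier) {
  codes <- carrier$codes
  if (!identical(codes, partner$codes) || !identical(codes, motif$codes))
    stop("motif, partner and carrier profiles must share one catalog")
  u <- carrier$presence == 1L
  if (!any(u)) stop("empty universe: carrier protein present nowhere")
  if (any(motif$presence > carrier$presence))
    stop("motif presence outside the carrier profile (no ortholog there)")
  mp <- motif$presence[u]; pp <- partner$presence[u]
  N <- sum(u); K <- sum(pp); n <- sum(mp); k <- sum(mp & pp)
  r <- if (N >= 2) as.numeric(profile_pearson(mp, pp)) else NA_real_
  structure(list(N = N, K = K, n = n, k = k,
                 p_value = hypergeom_tail(N, K, n, k), r = r),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf(
    "Co-occurrence in %d carrier species: partner %d, motif %d, both %d\n",
    x$N, x$K, x$n, x$k))
  cat(sprintf("  hypergeometric P(X >= k) = %.4g; phi r = %.3f\n",
              x$p_value, x$r))
  invisible(x)
}
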