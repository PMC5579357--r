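# Shared fixtures and independent oracles, built in code at test time.

# four-taxon balanced tree ((A,B),(C,D)) with code-style labels
toy_tree4 <- function() {
  tree <- ape::read.tree(text = "((Aaaa,Bbbb),(Cccc,Dddd));")
  tree
}

toy_catalog4 <- function() species_catalog(c("Aaaa", "Bbbb", "Cccc", "Dddd"))

# profile over toy_catalog4 from a plain 0/1 vector (order A,B,C,D)
toy_profile <- function(name, bits, catalog = toy_catalog4()) {
  phylo_profile(name, bits, catalog)
}

# independent phi-coefficient oracle from the 2x2 contingency table
phi_from_table <- function(x, y) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  den <- sqrt((a + b) * (c + d) * (a + c) * (b + d))
  (a * d - b * c) / den
}

# exhaustive hypergeometric tail: enumerate all C(N, n) draws of species and
# count those containing >= k of the K marked ones
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# exhaustive threshold-sweep oracle on an explicit pair table
sweep_oracle <- function(pair_r, is_ref, fold) {
  base <- mean(is_ref)
  best <- -1
  for (t in sort(unique(pair_r))) {
    sel <- pair_r >= t
    if ((sum(is_ref & sel) / sum(sel)) / base >= fold) {
      best <- t
      break
    }
  }
  best
}

# hand-assembled correlation-matrix object for calibration tests
# (4 proteins A..D with the worked pairwise r values)
worked_cm4 <- function() {
  prot <- c("A", "B", "C", "D")
  r <- matrix(0, 4, 4, dimnames = list(prot, prot))
  diag(r) <- 1
  set_r <- function(i, j, v) {
    r[i, j] <<- v; r[j, i] <<- v
  }
  set_r("A", "B", 0.9); set_r("C", "D", 0.8); set_r("A", "C", 0.5)
  set_r("A", "D", 0.3); set_r("B", "C", 0.2); set_r("B", "D", 0.1)
  structure(list(proteins = prot, r = r,
                 constant = stats::setNames(rep(FALSE, 4), prot)),
            class = "coev_cor")
}

# random binary profiles (non-constant unless allowed) over a catalog
random_profiles <- function(n_prof, catalog, p = 0.5, allow_constant = FALSE) {
  ns <- length(catalog$codes)
  lapply(seq_len(n_prof), function(i) {
    repeat {
      bits <- stats::rbinom(ns, 1, p)
      if (allow_constant || length(unique(bits)) > 1) break
    }
    phylo_profile(paste0("p", i), bits, catalog)
  })
}

# write an orthogroup FASTA to a temp file, returning its path
write_temp_fasta <- function(ids, seqs = NULL, stem = "group") {
  if (is.null(seqs)) seqs <- rep(strrep("ACDEF", 10), length(ids))
  path <- file.path(withr_tempdir <- tempfile(pattern = "fa"), paste0(stem, ".fasta"))
  dir.create(dirname(path), showWarnings = FALSE)
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
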