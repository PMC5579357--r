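#' Define an ordered species catalog
#'
#' A species catalog fixes the ordered set of genomes over which every
#' phylogenetic profile in an analysis is defined. Species are identified by
#' four-letter codes built from the first letter of the genus and the first
#' three letters of the species epithet (e.g. `"Hsap"` for *Homo sapiens*).
#' All profile, tree and motif operations in this package align their vectors
#' to the catalog's code order, so the catalog must be constructed once and
#' reused.
#'
#' Codes are matched case-sensitively: lower-casing could merge two distinct
#' species whose codes differ only in case. Duplicate codes (two species that
#' happen to collapse to the same four letters) are rejected outright, since
#' downstream profiles cannot distinguish them.
#'
#' @param codes Character vector of unique 4-letter species codes; the order
#'   given here is the canonical profile order.
#' @param species_names Optional character vector of full species names,
#'   parallel to `codes`.
#' @param supergroup Optional character vector of supergroup labels
#'   (e.g. Opisthokonta, Amoebozoa, Archaeplastida, SAR, Excavata), parallel
#'   to `codes`.
#' @return An object of class `"species_catalog"` with elements `codes`,
#'   `species_names` and `supergroup` (the latter two named by code).
#' @examples
#' cat4 <- species_catalog(c("Hsap", "Scer", "Atha", "Tthe"))
#' cat4
#' @export
species_catalog <- function(codes, species_names = NULL, supergroup = NULL) {
  if (!is.character(codes) || length(codes) == 0)
    stop("`codes` must be a non-empty character vector")
  bad <- codes[!grepl("^[A-Za-z]{4}$", codes)]
  if (length(bad) > 0)
    stop("species codes must be exactly 4 letters; offending: ",
         paste(bad, collapse = ", "))
  dup <- unique(codes[duplicated(codes)])
  if (length(dup) > 0)
    stop("species code collision (codes must be unique): ",
         paste(dup, collapse = ", "))
  set_aux <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) != length(codes))
      stop("`", what, "` must be parallel to `codes`")
    stats::setNames(as.character(x), codes)
  }
  structure(
    list(codes = codes,
         species_names = set_aux(species_names, "species_names"),
         supergroup = set_aux(supergroup, "supergroup")),
    class = "species_catalog")
}

#' @export
print.species_catalog <- function(x, ...) {
  cat("Species catalog with", length(x$codes), "species\n")
  cat("  codes:", paste(utils::head(x$codes, 8), collapse = " "),
      if (length(x$codes) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
length.species_catalog <- function(x) length(x$codes)

#' Extract the species code from a sequence identifier
#'
#' Sequence identifiers follow the convention of a 4-letter species code
#' followed by six digits (e.g. `"Hsap000123"`). The species code is the
#' first four characters. Identifiers that do not match the pattern are
#' rejected with the offending identifier named in the error.
#'
#' @param seq_id Character vector of sequence identifiers.
#' @return Character vector of 4-letter species codes.
#' @examples
#' parse_species_code(c("Hsap000123", "Scer999999"))
#' @export
parse_species_code <- function(seq_id) {
  if (!is.character(seq_id))
    stop("`seq_id` must be character")
  ok <- grepl("^[A-Za-z]{4}[0-9]{6}$", seq_id)
  if (!all(ok))
    stop("malformed sequence id(s) (expected 4 letters + 6 digits): ",
         paste(seq_id[!ok], collapse = ", "))
  substr(seq_id, 1L, 4L)
}

#' Build a species catalog from a tree's tip labels
#'
#' Convenience constructor taking the catalog order from the tip order of a
#' rooted species tree, so that adjacent positions in every profile
#' correspond to related species.
#'
#' @param tree An `ape::phylo` tree whose tip labels are 4-letter species codes.
#' @return A [species_catalog()].
#' @export
catalog_from_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  species_catalog(tree$tip.label)
}
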