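#' Orthologous groups and phylogenetic profiles
#'
#' An orthologous group (orthogroup) is the set of protein sequences, across
#' species, descending from a single gene in their common ancestor. Its
#' phylogenetic profile is the binary presence/absence vector of the group
#' over the ordered species catalog, with a parallel copy-number vector
#' (number of member sequences per species). A species is scored present
#' whether the gene is single- or multi-copy.
#'
#' @name phylo_profile
NULL

#' Construct an orthogroup from sequence records
#'
#' @param protein_name Label of the protein/orthogroup (non-empty).
#' @param ids Character vector of sequence identifiers (4-letter code +
#'   6 digits). May be empty for a protein absent everywhere.
#' @param sequences Optional character vector of amino-acid sequences,
#'   parallel to `ids`.
#' @return An object of class `"orthogroup"`.
#' @export
orthogroup <- function(protein_name, ids, sequences = NULL) {
  if (!is.character(protein_name) || length(protein_name) != 1 ||
      !nzchar(protein_name))
    stop("`protein_name` must be a non-empty string")
  ids <- as.character(ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate sequence ids in orthogroup '", protein_name, "': ",
         paste(dup, collapse = ", "))
  if (length(ids) > 0)
    parse_species_code(ids)  # validates the id pattern
  if (!is.null(sequences)) {
    if (length(sequences) != length(ids))
      stop("`sequences` must be parallel to `ids`")
    if (any(!nzchar(sequences)))
      stop("empty sequence in orthogroup '", protein_name, "'")
    sequences <- stats::setNames(toupper(as.character(sequences)), ids)
  }
  structure(list(protein_name = protein_name, ids = ids,
                 sequences = sequences),
            class = "orthogroup")
}

#' @export
print.orthogroup <- function(x, ...) {
  cat("Orthogroup", x$protein_name, "with", length(x$ids), "members\n")
  invisible(x)
}

#' Read one orthogroup from a FASTA file
#'
#' The first whitespace-delimited token of each FASTA header is taken as the
#' sequence identifier; the protein name defaults to the file name without
#' extension. Empty files and duplicated identifiers are errors.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param protein_name Protein label; defaults to the file name stem.
#' @return An [orthogroup()].
#' @export
read_orthogroup_fasta <- function(path, protein_name = NULL) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (is.null(protein_name))
    protein_name <- sub("\\.[^.]*$", "", basename(path))
  orthogroup(protein_name, ids, as.character(aa))
}

#' Construct a phylogenetic profile directly
#'
#' @param protein_name Protein label.
#' @param copy_number Non-negative integer vector of per-species copy counts,
#'   aligned to `catalog` order.
#' @param catalog A [species_catalog()].
#' @return Object of class `"phylo_profile"` with fields `protein_name`,
#'   `codes`, `presence` (0/1 integer vector) and `copy_number`, the vectors
#'   named by species code. The presence vector is by construction exactly
#'   the support of the copy-number vector.
#' @export
phylo_profile <- function(protein_name, copy_number, catalog) {
  stopifnot(inherits(catalog, "species_catalog"))
  if (length(copy_number) != length(catalog$codes))
    stop("copy_number length (", length(copy_number),
         ") does not match catalog size (", length(catalog$codes), ")")
  if (any(is.na(copy_number)) || any(copy_number < 0) ||
      any(copy_number != round(copy_number)))
    stop("copy_number must be non-negative integers")
  cn <- stats::setNames(as.integer(copy_number), catalog$codes)
  structure(list(protein_name = protein_name,
                 codes = catalog$codes,
                 presence = stats::setNames(as.integer(cn >= 1L), catalog$codes),
                 copy_number = cn),
            class = "phylo_profile")
}

#' @export
print.phylo_profile <- function(x, ...) {
  cat("Phylogenetic profile of", x$protein_name, "over", length(x$codes),
      "species\n")
  cat("  present in", sum(x$presence), "species;",
      sum(x$copy_number > 1L), "multi-copy\n")
  cat("  ", paste(x$presence, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Build a phylogenetic profile from an orthogroup
#'
#' Each member identifier is resolved to its species code; the copy number of
#' a species is the number of members carrying its code and presence is the
#' indicator of copy number >= 1. In strict mode (default) a member whose
#' code is not in the catalog is an error; in lenient mode it is skipped with
#' a warning.
#'
#' @param group An [orthogroup()].
#' @param catalog A [species_catalog()].
#' @param strict If `TRUE` (default), unknown species codes abort; if
#'   `FALSE`, they are dropped with a warning.
#' @return A [phylo_profile()].
#' @examples
#' cat3 <- species_catalog(c("Hsap", "Scer", "Atha"))
#' og <- orthogroup("Ndc80", c("Hsap000001", "Hsap000002", "Scer000003"))
#' build_profile(og, cat3)$copy_number
#' @export
build_profile <- function(group, catalog, strict = TRUE) {
  stopifnot(inherits(group, "orthogroup"), inherits(catalog, "species_catalog"))
  codes <- if (length(group$ids) > 0) parse_species_code(group$ids) else character(0)
  unknown <- setdiff(codes, catalog$codes)
  if (length(unknown) > 0) {
    msg <- paste0("orthogroup '", group$protein_name,
                  "' has members from species not in the catalog: ",
                  paste(unknown, collapse = ", "))
    if (strict) stop(msg)
    warning(msg, " (skipped)")
    codes <- codes[codes %in% catalog$codes]
  }
  cn <- table(factor(codes, levels = catalog$codes))
  phylo_profile(group$protein_name, as.integer(cn), catalog)
}

#' Read a rooted species tree and validate it against a catalog
#'
#' Parses a newick file with [ape::read.tree()], requires the tree to be
#' rooted (a basal bifurcation or explicit root edge) and its leaves to be a
#' subset of the catalog codes. Soft polytomies are preserved as-is.
#'
#' @param path Path to a newick file.
#' @param catalog A [species_catalog()].
#' @return An `ape::phylo` tree.
#' @export
read_species_tree <- function(path, catalog) {
  stopifnot(inherits(catalog, "species_catalog"))
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  validate_species_tree(tree, catalog)
}

#' @rdname read_species_tree
#' @param tree An `ape::phylo` object to validate in place.
#' @export
validate_species_tree <- function(tree, catalog) {
  stopifnot(inherits(tree, "phylo"), inherits(catalog, "species_catalog"))
  if (!ape::is.rooted(tree))
    stop("species tree is unrooted; please root it (e.g. ape::root) before use")
  unknown <- setdiff(tree$tip.label, catalog$codes)
  if (length(unknown) > 0)
    stop("tree leaves not in the species catalog: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(tree$tip.label))
    stop("duplicated leaf labels in species tree")
  tree
}

#' Stack profiles into a copy-number or presence matrix
#'
#' @param profiles List of [phylo_profile()] objects sharing one catalog.
#' @param what `"copy_number"` or `"presence"`.
#' @return Integer matrix, rows = proteins, columns = species codes.
#' @export
profile_matrix <- function(profiles, what = c("copy_number", "presence")) {
  what <- match.arg(what)
  .check_shared_catalog(profiles)
  m <- do.call(rbind, lapply(profiles, function(p) p[[what]]))
  rownames(m) <- vapply(profiles, function(p) p$protein_name, character(1))
  m
}

.check_shared_catalog <- function(profiles) {
  if (length(profiles) == 0) stop("empty profile list")
  if (!all(vapply(profiles, inherits, logical(1), "phylo_profile")))
    stop("all elements must be phylo_profile objects")
  codes <- profiles[[1]]$codes
  same <- vapply(profiles, function(p) identical(p$codes, codes), logical(1))
  if (!all(same)) stop("profiles do not share a common species catalog")
  invisible(codes)
}

#' Write and read a profile (copy-number) matrix as TSV
#'
#' The on-disk format is a tab-delimited table with a `protein` column and
#' one column per species code in catalog order; cells are copy numbers
#' (presence is their support, so the binary view is implied). The
#' write/read pair round-trips exactly.
#'
#' @param profiles List of [phylo_profile()] sharing one catalog; may be
#'   empty, yielding a header-only file.
#' @param path Output (or input) TSV path.
#' @return `write_profile_matrix` invisibly returns `path`;
#'   `read_profile_matrix` returns a named list of [phylo_profile()].
#' @export
write_profile_matrix <- function(profiles, path) {
  if (length(profiles) == 0) {
    writeLines("protein", path)
    return(invisible(path))
  }
  m <- profile_matrix(profiles, "copy_number")
  df <- data.frame(protein = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (names(df)[1] != "protein")
    stop("profile matrix must have a leading 'protein' column")
  codes <- names(df)[-1]
  if (nrow(df) == 0) return(list())
  catalog <- species_catalog(codes)
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num)) || any(num != round(num)) || any(num < 0))
    stop("profile matrix cells must be non-negative integers")
  out <- lapply(seq_len(nrow(df)), function(i)
    phylo_profile(df$protein[i], as.integer(num[i, ]), catalog))
  stats::setNames(out, df$protein)
}

#' Build profiles for a directory of orthogroup FASTA files
#'
#' Reads every `*.fa`/`*.fasta` file in `dir` as one orthogroup (protein name
#' = file stem) and builds its phylogenetic profile.
#'
#' @param dir Directory of orthogroup FASTA files.
#' @param catalog A [species_catalog()].
#' @param strict Passed to [build_profile()].
#' @return Named list of [phylo_profile()].
#' @export
build_profiles_dir <- function(dir, catalog, strict = TRUE) {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (length(files) == 0) stop("no FASTA files in ", dir)
  profs <- lapply(files, function(f)
    build_profile(read_orthogroup_fasta(f), catalog, strict = strict))
  stats::setNames(profs, vapply(profs, function(p) p$protein_name, character(1)))
}
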