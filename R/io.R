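#' Read a FASTA file of (mi)RNA or DNA sequences
#'
#' Sequences are upper-cased; with `alphabet = "rna"` any `T` is normalised
#' to `U` so all downstream sequence comparisons run in the RNA alphabet.
#' Record order is preserved.
#'
#' @param path FASTA file.
#' @param alphabet `"rna"`, `"dna"` or `"either"`.
#' @return Named character vector, names = record ids (first word of the
#'   header), values = sequences.
#' @export
read_fasta <- function(path, alphabet = c("rna", "dna", "either")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "rna") seqs <- gsub("T", "U", seqs, fixed = TRUE)
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read a BED6 file of genomic intervals
#'
#' Coordinates are kept 0-based half-open exactly as in BED. Validation is
#' strict: six columns, `start < end`, strand `+` or `-`; offending lines
#' are reported by number.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return data.frame with columns `name`, `scaffold`, `start`, `end`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character", "character"))
  if (ncol(bed) < 6) stop("BED6 requires 6 columns (strand column missing?)")
  names(bed)[1:6] <- c("scaffold", "start", "end", "name", "score", "strand")
  bad <- which(bed$start >= bed$end)
  if (length(bad) > 0) {
    stop("start >= end at line ", bad[1], " of ", path)
  }
  badstrand <- which(!bed$strand %in% c("+", "-"))
  if (length(badstrand) > 0) {
    stop("strand not in {+,-} at line ", badstrand[1], " of ", path)
  }
  bed[, c("name", "scaffold", "start", "end", "score", "strand")]
}

#' Write intervals as BED6
#'
#' @param bed data.frame as returned by [read_bed()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  out <- data.frame(bed$scaffold, bed$start, bed$end, bed$name,
                    if (is.null(bed$score)) 0 else bed$score, bed$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a rooted species tree with branch lengths
#'
#' The tree must be strictly bifurcating (including the root) and carry a
#' branch length on every edge — lengths are required downstream by the
#' independent-contrast machinery.
#'
#' @param path newick file containing a single tree.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick tree from ", path)
  validate_species_tree(tr)
  tr
}

#' Validate the structural invariants of a species tree
#'
#' @param tr a `phylo` object.
#' @return `tr`, invisibly; errors on violation.
#' @export
validate_species_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    stop("tree must be rooted and strictly bifurcating (root with 2 children)")
  }
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge)) {
    stop("every branch must carry a length")
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  invisible(tr)
}

#' Write a species tree to newick
#'
#' @param tr `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_species_tree <- function(tr, path) {
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Read an aligned multi-species 3' UTR FASTA
#'
#' All records must have equal aligned length; the gap character is `-`.
#' Records named for species absent from `tree_tips` (when supplied) trigger
#' a warning but are retained — orthologue sets need not cover every tip.
#'
#' @param path aligned FASTA, one record per species.
#' @param tree_tips optional character vector of valid species names.
#' @return list with `aln` (named character vector, RNA alphabet),
#'   `n_col` (alignment columns) and `ungapped_lengths` (named integer).
#' @export
read_alignment <- function(path, tree_tips = NULL) {
  aln <- read_fasta(path, alphabet = "rna")
  widths <- nchar(aln)
  if (length(unique(widths)) != 1) {
    stop("aligned sequences have unequal lengths in ", path)
  }
  if (!is.null(tree_tips)) {
    unknown <- setdiff(names(aln), tree_tips)
    if (length(unknown) > 0) {
      warning("species not on the tree: ", paste(unknown, collapse = ", "))
    }
  }
  ungapped <- nchar(gsub("-", "", aln, fixed = TRUE))
  list(aln = aln, n_col = unname(widths[1]), ungapped_lengths = ungapped)
}

#' Read a feature-by-sample expression matrix from TSV
#'
#' @param path TSV with feature ids in the first column and one column per
#'   sample.
#' @return numeric matrix, rownames = features, colnames = samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative expression values in ", path)
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output file.
#' @param id_col header for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV (no quoting, no row names)
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
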