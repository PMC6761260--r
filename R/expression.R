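#' TPM normalisation of an mRNA count matrix
#'
#' Transcripts per million: counts are divided by feature length, then each
#' sample is scaled so its column sums to 10^6.
#'
#' @param counts feature-by-sample matrix of non-negative counts.
#' @param lengths named numeric vector of feature lengths in nt (> 0),
#'   covering every row of `counts`.
#' @return matrix of TPM values; every column sums to 10^6.
#' @export
tpm_normalize <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!all(rownames(counts) %in% names(lengths))) {
    stop("missing feature length(s)")
  }
  len <- as.vector(lengths[rownames(counts)])
  if (any(len <= 0)) stop("zero or negative feature length")
  rate <- counts / len
  tot <- colSums(rate)
  zero <- which(tot == 0)
  if (length(zero) > 0) {
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(rate, 2, tot, `/`) * 1e6
}

#' RPM normalisation of a small-RNA count matrix
#'
#' Reads per million mapped: each sample's counts are scaled by its library
#' size to sum to 10^6. No length correction — mature miRNAs are of nearly
#' constant length.
#'
#' @param counts feature-by-sample matrix of non-negative counts.
#' @return matrix of RPM values; every column sums to 10^6.
#' @export
rpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  zero <- which(tot == 0)
  if (length(zero) > 0) {
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, tot, `/`) * 1e6
}

#' Pearson correlation of functional miRNA-mRNA pairs across individuals
#'
#' For each (miRNA gene, target gene) pair the two expression vectors are
#' taken over the shared samples, optionally log2(x+1)-transformed, and
#' correlated. Pairs with zero variance in either vector are reported with
#' `r = NA` so they can be excluded from sign counts.
#'
#' @param mirna_expr,mrna_expr normalised feature-by-sample matrices sharing
#'   sample columns (>= 3 shared samples).
#' @param pairs data.frame with columns `mirna_gene` and `target_gene`.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return data.frame: `mirna_gene`, `target_gene`, `r`, `p`, `n`.
#' @export
pair_correlations <- function(mirna_expr, mrna_expr, pairs,
                              transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  mi <- mirna_expr[, shared, drop = FALSE]
  mr <- mrna_expr[, shared, drop = FALSE]
  if (transform == "log2p1") {
    mi <- log2(mi + 1)
    mr <- log2(mr + 1)
  }
  pairs <- unique(pairs[, c("mirna_gene", "target_gene")])
  keep <- pairs$mirna_gene %in% rownames(mi) &
    pairs$target_gene %in% rownames(mr)
  pairs <- pairs[keep, , drop = FALSE]
  n <- length(shared)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- mi[pairs$mirna_gene[i], ]
    y <- mr[pairs$target_gene[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    r <- stats::cor(x, y)
    # t-distribution p-value with n-2 df
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
  })
  res <- do.call(rbind, res)
  data.frame(pairs, r = res[, "r"], p = res[, "p"], n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Phylogenetically independent contrasts of tip values
#'
#' Felsenstein's pruning: each internal node contributes the standardized
#' difference of its daughters, `(x_i - x_j) / sqrt(b_i + b_j)`, ancestral
#' values are branch-length-weighted means, and the parent branch is
#' extended by `b_i b_j / (b_i + b_j)`.
#'
#' @param tree rooted binary `phylo` with strictly positive branch lengths.
#' @param tip_values named numeric vector covering every tip.
#' @return data.frame with `node` (internal node number), `contrast`
#'   (standardized) and `variance` (sum of adjusted branch lengths), one row
#'   per internal node.
#' @export
pic_contrasts <- function(tree, tip_values) {
  validate_species_tree(tree)
  if (!all(tree$tip.label %in% names(tip_values))) {
    stop("missing tip value(s): ",
         paste(setdiff(tree$tip.label, names(tip_values)), collapse = ", "))
  }
  if (any(tree$edge.length <= 0)) stop("zero branch length: contrasts undefined")
  x <- tip_values[tree$tip.label]
  pc <- ape::pic(x, tree, scaled = TRUE, var.contrasts = TRUE)
  data.frame(node = as.integer(rownames(pc)),
             contrast = unname(pc[, "contrasts"]),
             variance = unname(pc[, "variance"]),
             row.names = NULL)
}

#' Correlation of two contrast vectors through the origin
#'
#' Contrasts have arbitrary sign, so the correlation is computed without
#' intercept: `r = sum(xy) / sqrt(sum(x^2) sum(y^2))`.
#'
#' @param contrasts_x,contrasts_y numeric vectors over the same node set.
#' @return correlation in \[-1, 1\], or `NA` when either vector is all-zero.
#' @export
pic_correlation <- function(contrasts_x, contrasts_y) {
  if (length(contrasts_x) != length(contrasts_y)) stop("length mismatch")
  sxx <- sum(contrasts_x^2)
  syy <- sum(contrasts_y^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sum(contrasts_x * contrasts_y) / sqrt(sxx * syy)
}

#' Test for an excess of negative correlations
#'
#' Goodness-of-fit of the (negative, positive) sign counts against a 50:50
#' expectation, df = 1, no continuity correction. `NA` correlations are
#' dropped and exact zeros excluded.
#'
#' @param correlations numeric vector of correlation coefficients.
#' @return list with `n_negative`, `n_positive` and `test` (an `mc_test`).
#' @export
sign_bias_test <- function(correlations) {
  r <- correlations[!is.na(correlations) & correlations != 0]
  if (length(r) < 2) stop("fewer than 2 usable correlations")
  n_neg <- sum(r < 0)
  n_pos <- sum(r > 0)
  list(n_negative = n_neg, n_positive = n_pos,
       test = chi2_gof(c(n_neg, n_pos), c(0.5, 0.5)))
}

#' Per-species mean expression on the contrast scale
#'
#' Averages log2(x+1) normalised expression over each species' individuals —
#' the tip values fed to [pic_contrasts()] for across-species correlation.
#'
#' @param expr normalised feature-by-sample matrix.
#' @param species_of_sample named character vector mapping sample to species.
#' @return feature-by-species matrix of mean log2(x+1) values.
#' @export
species_mean_expression <- function(expr, species_of_sample) {
  if (!all(colnames(expr) %in% names(species_of_sample))) {
    stop("sample(s) without species assignment")
  }
  sp <- species_of_sample[colnames(expr)]
  lx <- log2(expr + 1)
  cols <- lapply(sort(unique(sp)), function(s) {
    rowMeans(lx[, sp == s, drop = FALSE])
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(rownames(expr), sort(unique(sp)))
  out
}
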