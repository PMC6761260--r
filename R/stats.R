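#' Construct a test-result record
#'
#' Light container used by all hypothesis tests in the package so downstream
#' tables carry the statistic, degrees of freedom, p-value and the exact
#' method variant that produced them.
#'
#' @param statistic numeric test statistic.
#' @param df degrees of freedom, or `NA` where the test has none.
#' @param p_value p-value in \[0, 1\].
#' @param method character string naming the exact variant (e.g. `"chi2_yates"`).
#' @param n integer vector of sample sizes entering the test.
#' @return A list of class `mc_test` with the above fields.
#' @keywords internal
test_result <- function(statistic, df, p_value, method, n) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), method = method, n = n),
    class = "mc_test"
  )
}

#' @export
print.mc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g, n = %s\n",
              x$method, x$statistic,
              if (is.na(x$df)) "NA" else format(x$df),
              x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The U statistic uses midranks for
#' ties. The p-value is exact (full permutation distribution) when the
#' combined sample size is at most 10 and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. The switch point is recorded in the method string.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return An `mc_test` with the U statistic for `x`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 10) && !ties
  wt <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = exact, correct = TRUE)
  test_result(statistic = wt$statistic, df = NA_real_, p_value = wt$p.value,
              method = if (exact) "mann_whitney_u_exact" else
                "mann_whitney_u_normal_tie_corrected",
              n = c(length(x), length(y)))
}

#' Chi-square test on a 2x2 contingency table
#'
#' With `yates = TRUE` (default) the correction term is clamped at zero,
#' `sum(max(|O - E| - 0.5, 0)^2 / E)`, so near-null tables cannot have their
#' statistic inflated by the correction.
#'
#' @param table 2x2 matrix of non-negative integer counts; all margins must
#'   be positive.
#' @param yates apply the continuity correction (default `TRUE`).
#' @return An `mc_test` with df = 1.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  test_result(statistic = ct$statistic, df = 1, p_value = ct$p.value,
              method = if (yates) "chi2_yates" else "chi2_uncorrected",
              n = sum(table))
}

#' Chi-square goodness-of-fit test
#'
#' @param observed non-negative counts.
#' @param expected_probs probabilities summing to 1; no category may have
#'   zero expectation.
#' @return An `mc_test` with df = k - 1.
#' @export
chi2_gof <- function(observed, expected_probs) {
  if (length(observed) != length(expected_probs)) stop("length mismatch")
  if (abs(sum(expected_probs) - 1) > 1e-8) stop("expected_probs must sum to 1")
  if (any(expected_probs <= 0)) stop("zero expected count in a category")
  if (any(observed < 0)) stop("negative observed count")
  ct <- suppressWarnings(stats::chisq.test(observed, p = expected_probs))
  test_result(statistic = ct$statistic, df = length(observed) - 1,
              p_value = ct$p.value, method = "chi2_gof", n = sum(observed))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided. When both samples are constant and share the same mean the
#' comparison is vacuous and p = 1 is returned by convention.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return An `mc_test`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(test_result(0, NA_real_, 1, "welch_t_degenerate",
                         c(length(x), length(y))))
    }
    stop("both samples constant with different means: t undefined")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  test_result(statistic = tt$statistic, df = tt$parameter,
              p_value = tt$p.value, method = "welch_t",
              n = c(length(x), length(y)))
}

#' One-sided hypergeometric over-representation test
#'
#' Probability of observing `k` or more annotated genes in a test set of
#' size `n` drawn from a baseline of `N` genes of which `K` are annotated
#' (Fisher's exact test, upper tail).
#'
#' @param k hits in the test set.
#' @param n test-set size.
#' @param K hits in the baseline set.
#' @param N baseline-set size.
#' @return An `mc_test` with the hypergeometric upper-tail p-value.
#' @export
fisher_enrichment <- function(k, n, K, N) {
  if (k > min(n, K) || n > N || K > N || any(c(k, n, K, N) < 0)) {
    stop("inconsistent hypergeometric counts")
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  test_result(statistic = k, df = NA_real_, p_value = p,
              method = "fisher_exact_upper", n = c(k = k, n = n, K = K, N = N))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' GO term over-representation analysis
#'
#' One hypergeometric test per GO term with at least one test-set hit,
#' followed by Benjamini-Hochberg correction across the tested terms.
#'
#' @param test_genes character vector; must be a subset of `baseline_genes`.
#' @param baseline_genes character vector of all genes in the universe.
#' @param annotation data.frame with columns `gene_id` and `go_id` (one row
#'   per gene-term link), or a named list mapping gene id to a character
#'   vector of terms.
#' @return data.frame with columns `term`, `k`, `n`, `K`, `N`, `p`, `q`,
#'   sorted by `p` then `term`.
#' @export
go_enrichment <- function(test_genes, baseline_genes, annotation) {
  test_genes <- unique(test_genes)
  baseline_genes <- unique(baseline_genes)
  if (length(test_genes) == 0) stop("empty test set")
  if (!all(test_genes %in% baseline_genes)) {
    stop("test set must be a subset of the baseline set")
  }
  if (is.data.frame(annotation)) {
    stopifnot(all(c("gene_id", "go_id") %in% names(annotation)))
    ann <- annotation[annotation$gene_id %in% baseline_genes, , drop = FALSE]
  } else {
    ann <- data.frame(
      gene_id = rep(names(annotation), lengths(annotation)),
      go_id = unlist(annotation, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    ann <- ann[ann$gene_id %in% baseline_genes, , drop = FALSE]
  }
  if (nrow(ann) == 0) stop("annotation covers no baseline gene")
  ann <- unique(ann)
  N <- length(baseline_genes)
  n <- length(test_genes)
  terms <- split(ann$gene_id, ann$go_id)
  rows <- lapply(names(terms), function(tm) {
    genes <- terms[[tm]]
    k <- sum(test_genes %in% genes)
    if (k == 0) return(NULL)
    K <- length(unique(genes))
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p = fisher_enrichment(k, n, K, N)$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Principal component analysis of a feature-by-sample matrix
#'
#' Features (rows) are centred, the centred matrix is decomposed by SVD, and
#' the proportion of variance per component is returned together with sample
#' scores. The sign of each component is fixed so that its largest-magnitude
#' feature loading is positive; a matrix with zero total variance yields
#' all-zero shares and scores rather than an error.
#'
#' @param x numeric matrix, features in rows, samples in columns (>= 2
#'   samples).
#' @return list with `variance_explained` (length = number of components)
#'   and `scores` (samples x components, rownames = sample ids).
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 samples")
  xc <- x - rowMeans(x)
  ncomp <- min(dim(x)) - as.integer(nrow(x) >= ncol(x))
  ncomp <- max(ncomp, 1L)
  total_var <- sum(xc^2)
  if (total_var == 0) {
    k <- min(ncol(x) - 1L, nrow(x))
    return(list(variance_explained = rep(0, k),
                scores = matrix(0, ncol(x), k,
                                dimnames = list(colnames(x), NULL))))
  }
  sv <- svd(xc)
  keep <- sv$d > sv$d[1] * 1e-12
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (i in seq_along(d)) {
    j <- which.max(abs(u[, i]))
    if (u[j, i] < 0) {
      u[, i] <- -u[, i]
      v[, i] <- -v[, i]
    }
  }
  scores <- sweep(v, 2, d, `*`)
  rownames(scores) <- colnames(x)
  list(variance_explained = d^2 / sum(sv$d^2), scores = scores)
}
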