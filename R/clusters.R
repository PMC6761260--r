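#' Detect physical pre-miRNA clusters
#'
#' Within each (scaffold, strand) group, precursors are sorted by start and
#' chained whenever the intergenic gap to the previous precursor
#' (`next start - previous end`) is below `max_gap`. Chains of two or more
#' members are clusters; chaining is single-linkage, so a cluster's overall
#' span may exceed `max_gap`.
#'
#' @param premirnas data.frame with columns `name`, `scaffold`, `start`,
#'   `end`, `strand` (0-based half-open intervals, as from [read_bed()]).
#' @param max_gap maximum intergenic distance in bp (default 5000).
#' @return list with `clusters` (data.frame: `cluster_id`, `scaffold`,
#'   `strand`, `start`, `end`, `n`, `span_bp`, `density`, `members`
#'   comma-separated) and `membership` (named cluster id per precursor, NA
#'   for unclustered).
#' @export
detect_clusters <- function(premirnas, max_gap = 5000) {
  stopifnot(all(c("name", "scaffold", "start", "end", "strand") %in%
                  names(premirnas)))
  if (any(premirnas$start >= premirnas$end)) stop("invalid interval")
  membership <- stats::setNames(rep(NA_character_, nrow(premirnas)),
                                premirnas$name)
  rows <- list()
  groups <- split(premirnas,
                  paste(premirnas$scaffold, premirnas$strand, sep = "\r"))
  for (g in groups) {
    g <- g[order(g$start, g$end, g$name), , drop = FALSE]
    if (nrow(g) == 0) next
    gap <- g$start[-1] - g$end[-nrow(g)]
    chain <- cumsum(c(0, as.integer(gap >= max_gap)))
    for (ch in split(g, chain)) {
      if (nrow(ch) < 2) next
      span <- max(ch$end) - min(ch$start)
      id <- paste0("cl_", ch$scaffold[1], "_", ch$strand[1], "_", min(ch$start))
      membership[ch$name] <- id
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = id, scaffold = ch$scaffold[1], strand = ch$strand[1],
        start = min(ch$start), end = max(ch$end), n = nrow(ch),
        span_bp = span, density = nrow(ch) / (span / 1000),
        members = paste(sort(ch$name), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  clusters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cluster_id = character(), scaffold = character(),
               strand = character(), start = integer(), end = integer(),
               n = integer(), span_bp = integer(), density = numeric(),
               members = character(), stringsAsFactors = FALSE)
  clusters <- clusters[order(clusters$cluster_id), , drop = FALSE]
  rownames(clusters) <- NULL
  list(clusters = clusters, membership = membership)
}

#' Density of a pre-miRNA cluster
#'
#' Members per kilobase of cluster span (first start to last end).
#'
#' @param starts,ends member interval coordinates (>= 2 members).
#' @return density in pre-miRNAs per kb.
#' @export
cluster_density <- function(starts, ends) {
  if (length(starts) < 2) stop("a cluster needs >= 2 members")
  span <- max(ends) - min(starts)
  length(starts) / (span / 1000)
}

#' Label clusters by the conservation class of their members
#'
#' A cluster is labelled `conserved` or `non-conserved` only when all its
#' members share that class; otherwise `mixed`.
#'
#' @param clusterset output of [detect_clusters()].
#' @param premirna_class named character vector: class per precursor name.
#' @return the `clusters` data.frame with an added `class_label` column.
#' @export
label_clusters <- function(clusterset, premirna_class) {
  cl <- clusterset$clusters
  cl$class_label <- vapply(strsplit(cl$members, ",", fixed = TRUE),
                           function(m) {
                             u <- unique(premirna_class[m])
                             if (length(u) == 1 && !is.na(u)) u else "mixed"
                           }, "")
  cl
}

#' Compare clustered fractions between conservation classes
#'
#' Cross-tabulates precursors by class (conserved vs non-conserved) and
#' clustered status, and tests association with a Yates-corrected
#' chi-square.
#'
#' @param premirna_class named character vector of classes per precursor
#'   (`conserved` / `non-conserved`); other values are ignored.
#' @param clusterset output of [detect_clusters()] covering the same
#'   precursors.
#' @return list with `table` (2x2), `fractions` (percent clustered per
#'   class, 2 decimals) and `test` (an `mc_test`).
#' @export
clustered_fraction_test <- function(premirna_class, clusterset) {
  keep <- names(premirna_class)[premirna_class %in%
                                  c("conserved", "non-conserved")]
  if (length(keep) == 0) stop("no precursors in the two classes")
  clustered <- !is.na(clusterset$membership[keep])
  cls <- factor(premirna_class[keep], levels = c("conserved", "non-conserved"))
  tab <- matrix(0L, 2, 2, dimnames = list(levels(cls),
                                          c("clustered", "unclustered")))
  tab[, 1] <- tapply(clustered, cls, sum, default = 0L)
  tab[, 2] <- tapply(!clustered, cls, sum, default = 0L)
  if (any(rowSums(tab) == 0)) stop("empty conservation class")
  list(
    table = tab,
    fractions = round(100 * tab[, 1] / rowSums(tab), 2),
    test = chi2_2x2(tab, yates = TRUE)
  )
}

#' Compare cluster densities between two groups
#'
#' Two-sided Welch t-test of per-cluster densities (per kb), typically
#' all-conserved vs all-non-conserved clusters with mixed clusters excluded.
#'
#' @param densities_a,densities_b numeric vectors of per-cluster densities
#'   (>= 2 values each).
#' @return An `mc_test`.
#' @export
density_comparison <- function(densities_a, densities_b) {
  welch_t(densities_a, densities_b)
}
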