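#' Reverse complement in the RNA alphabet
#'
#' @param x RNA string(s) over `{A,C,G,U}`.
#' @return reverse complement, written 5' to 3'.
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Canonical seed-match strings of a mature miRNA
#'
#' The four canonical target-site types, written as the target-strand
#' sequence 5' to 3': `6mer` pairs miRNA positions 2-7, `7mer-m8` adds a
#' match to position 8, `7mer-A1` adds an `A` opposite position 1, and
#' `8mer` has both.
#'
#' @param mature RNA string, length >= 8.
#' @return named character vector with elements `6mer`, `7mer-m8`,
#'   `7mer-A1`, `8mer`.
#' @export
site_strings <- function(mature) {
  if (nchar(mature) < 8) stop("mature sequence shorter than 8 nt")
  six <- rna_revcomp(substr(mature, 2, 7))
  m8 <- chartr("ACGU", "UGCA", substr(mature, 8, 8))
  c("6mer" = six,
    "7mer-m8" = paste0(m8, six),
    "7mer-A1" = paste0(six, "A"),
    "8mer" = paste0(m8, six, "A"))
}

# Scan one mature miRNA against a character vector of ungapped UTRs.
# Anchored on 6mer occurrences; each locus is reported once with the
# strongest supported type (8mer > 7mer-m8 > 7mer-A1 > 6mer).
# Returns data.frame(utr = index, start = 0-based, length, site_type).
.scan_seed_many <- function(utrs, mature) {
  ss <- site_strings(mature)
  six <- ss[["6mer"]]
  m8c <- substr(ss[["7mer-m8"]], 1, 1)
  # zero-width lookahead finds overlapping occurrences too (a plain fixed
  # search would merge self-overlapping seed matches into one locus)
  hits <- gregexpr(paste0("(?=", six, ")"), utrs, perl = TRUE)
  rows <- lapply(seq_along(utrs), function(i) {
    p <- hits[[i]]
    if (p[1] == -1) return(NULL)
    p <- as.integer(p)
    prev <- substring(utrs[i], p - 1, p - 1)
    nxt <- substring(utrs[i], p + 6, p + 6)
    has_m8 <- p > 1 & prev == m8c
    has_a1 <- nxt == "A"
    type <- ifelse(has_m8 & has_a1, "8mer",
                   ifelse(has_m8, "7mer-m8",
                          ifelse(has_a1, "7mer-A1", "6mer")))
    start0 <- (p - 1L) - ifelse(has_m8, 1L, 0L)
    len <- 6L + as.integer(has_m8) + as.integer(has_a1)
    data.frame(utr = i, start = start0, length = len, site_type = type,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(utr = integer(), start = integer(), length = integer(),
                      site_type = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Find canonical seed-match sites of a miRNA in one ungapped UTR
#'
#' All offsets are scanned; each seed-match locus (6mer occurrence) is
#' reported once with the strongest supported site type, so a weaker type is
#' never emitted on the same seed window as a stronger one, while distinct
#' loci may overlap.
#'
#' @param utr ungapped RNA string (may be empty).
#' @param mature mature miRNA RNA string, length >= 8.
#' @return data.frame with `start` (0-based ungapped offset), `length`
#'   (6, 7 or 8) and `site_type`.
#' @export
find_seed_sites <- function(utr, mature) {
  if (length(utr) != 1) stop("one UTR at a time; see predict_target_sites()")
  if (nchar(utr) == 0) {
    return(data.frame(start = integer(), length = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  .scan_seed_many(utr, mature)[, c("start", "length", "site_type")]
}

# Column index of every ungapped position in a gapped sequence.
ungapped_to_columns <- function(gapped) {
  which(strsplit(gapped, "")[[1]] != "-")
}

#' Predict target sites of a miRNA catalog on per-gene UTR alignments
#'
#' Each species' UTR is taken from the gene's alignment (gaps removed) and
#' scanned with every miRNA gene carried by that species. Sites report both
#' ungapped coordinates and the alignment columns of the match window, plus
#' the relative position of the site midpoint along the UTR.
#'
#' @param alignments named list (by target gene id) of alignments as
#'   returned by [read_alignment()], or of named gapped character vectors.
#' @param catalog data.frame with one row per (miRNA gene, species):
#'   columns `gene_id`, `species`, `sequence` (a representative mature;
#'   isomiRs share the 2-8 region so any member gives identical sites).
#' @return data.frame: `target_gene`, `species`, `mirna_gene`, `site_type`,
#'   `start`, `length`, `col_first`, `col_last`, `utr_length`, `rel_pos`.
#' @export
predict_target_sites <- function(alignments, catalog) {
  stopifnot(all(c("gene_id", "species", "sequence") %in% names(catalog)))
  cat_rep <- catalog[!duplicated(paste(catalog$gene_id, catalog$species)), ]
  by_species <- split(cat_rep, cat_rep$species)
  gene_ids <- names(alignments)
  aln_of <- function(a) if (is.list(a)) a$aln else a
  # per species: ungapped UTRs + column maps for all genes carrying it
  out <- list()
  for (sp in names(by_species)) {
    has_sp <- vapply(alignments, function(a) sp %in% names(aln_of(a)), TRUE)
    if (!any(has_sp)) next
    idx <- which(has_sp)
    gapped <- vapply(alignments[idx], function(a) aln_of(a)[[sp]], "")
    utrs <- gsub("-", "", gapped, fixed = TRUE)
    colmaps <- lapply(gapped, ungapped_to_columns)
    ulen <- nchar(utrs)
    mir <- by_species[[sp]]
    for (k in seq_len(nrow(mir))) {
      hits <- .scan_seed_many(utrs, mir$sequence[k])
      if (nrow(hits) == 0) next
      cf <- integer(nrow(hits)); clast <- integer(nrow(hits))
      for (h in seq_len(nrow(hits))) {
        cm <- colmaps[[hits$utr[h]]]
        cf[h] <- cm[hits$start[h] + 1L]
        clast[h] <- cm[hits$start[h] + hits$length[h]]
      }
      ul <- ulen[hits$utr]
      out[[length(out) + 1]] <- data.frame(
        target_gene = gene_ids[idx][hits$utr], species = sp,
        mirna_gene = mir$gene_id[k], site_type = hits$site_type,
        start = hits$start, length = hits$length,
        col_first = cf, col_last = clast, utr_length = ul,
        rel_pos = relative_position(hits$start, hits$length, ul),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(target_gene = character(), species = character(),
               mirna_gene = character(), site_type = character(),
               start = integer(), length = integer(), col_first = integer(),
               col_last = integer(), utr_length = integer(),
               rel_pos = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Flag target sites conserved across all aligned species
#'
#' A site is conserved when every species present in that gene's alignment
#' carries a site of the same miRNA gene whose match window overlaps it by
#' at least `min_overlap` alignment columns (the site type may differ; a
#' one-column jitter of the alignment must not break the call).
#'
#' @param sites data.frame from [predict_target_sites()].
#' @param alignments the same alignments the sites were predicted on.
#' @param min_overlap minimum overlapping columns (default 6).
#' @return `sites` with an added logical `conserved_site` column.
#' @export
call_site_conservation <- function(sites, alignments, min_overlap = 6) {
  aln_of <- function(a) if (is.list(a)) a$aln else a
  sites$conserved_site <- FALSE
  if (nrow(sites) == 0) return(sites)
  key <- paste(sites$target_gene, sites$mirna_gene, sep = "\r")
  for (grp in split(seq_len(nrow(sites)), key)) {
    gene <- sites$target_gene[grp[1]]
    aln_species <- names(aln_of(alignments[[gene]]))
    if (is.null(aln_species)) stop("no alignment for gene ", gene)
    missing_sp <- setdiff(unique(sites$species[grp]), aln_species)
    if (length(missing_sp) > 0) {
      stop("alignment of ", gene, " lacks species with sites: ",
           paste(missing_sp, collapse = ", "))
    }
    sp_of <- sites$species[grp]
    if (!all(aln_species %in% sp_of)) next  # some species has no site
    cf <- sites$col_first[grp]; cl <- sites$col_last[grp]
    conserved <- rep(TRUE, length(grp))
    for (sp in aln_species) {
      other <- which(sp_of == sp)
      ok <- vapply(seq_along(grp), function(i) {
        any(pmin(cl[i], cl[other]) - pmax(cf[i], cf[other]) + 1 >= min_overlap)
      }, TRUE)
      conserved <- conserved & ok
    }
    sites$conserved_site[grp] <- conserved
  }
  sites
}

#' Relative position of a target site along its 3' UTR
#'
#' The site midpoint scaled to \[0, 1\]: 0 lies at the stop-codon end of the
#' UTR, 1 at the poly-A end.
#'
#' @param start 0-based ungapped start offset(s).
#' @param length site length(s) in nt.
#' @param utr_length ungapped UTR length(s), >= `length`.
#' @return numeric in \[0, 1\].
#' @export
relative_position <- function(start, length, utr_length) {
  if (any(utr_length < length)) stop("UTR shorter than site")
  denom <- pmax(utr_length - 1, 1)
  ifelse(utr_length == length, 0.5, (start + (length - 1) / 2) / denom)
}

#' Kernel density profile of target-site relative positions
#'
#' Gaussian kernel density with Silverman's reference bandwidth
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)` (R's default `bw.nrd0`), evaluated
#' on an even grid over \[0, 1\].
#'
#' @param positions relative positions in \[0, 1\]; at least two distinct
#'   values.
#' @param n_grid number of grid points (default 512).
#' @return list with `grid`, `density` and `bw`.
#' @export
spatial_profile <- function(positions, n_grid = 512) {
  positions <- positions[!is.na(positions)]
  if (length(unique(positions)) < 2) {
    stop("need >= 2 distinct positions (bandwidth would be 0)")
  }
  bw <- stats::bw.nrd0(positions)
  d <- stats::density(positions, bw = bw, from = 0, to = 1, n = n_grid)
  list(grid = d$x, density = d$y, bw = bw)
}

#' Linear-regression slope of a density profile over an interior window
#'
#' Ordinary least squares of density on position restricted to
#' `lo <= x <= hi` (default the 10-90% window, which keeps the estimate
#' clear of kernel edge effects).
#'
#' @param grid,density vectors from [spatial_profile()].
#' @param lo,hi window bounds (defaults 0.1, 0.9).
#' @return list with `slope` and `intercept`.
#' @export
density_slope <- function(grid, density, lo = 0.1, hi = 0.9) {
  keep <- grid >= lo & grid <= hi
  if (sum(keep) < 3) stop("fewer than 3 grid points in the window")
  fit <- stats::lm(density[keep] ~ grid[keep])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Split genes into long- and short-UTR sets
#'
#' `long` holds genes whose UTR length is strictly greater than the median;
#' everything else is `short`, so ties at the median fall into `short` and
#' the split is deterministic.
#'
#' @param lengths named numeric vector of UTR lengths (>= 2 genes).
#' @return list with character vectors `long` and `short`.
#' @export
split_by_length <- function(lengths) {
  if (length(lengths) < 2) stop("need >= 2 genes")
  med <- stats::median(lengths)
  list(long = sort(names(lengths)[lengths > med]),
       short = sort(names(lengths)[lengths <= med]))
}

#' Emergence rate of species-specific target sites per gene
#'
#' For each target gene: the number of sites whose miRNA gene is
#' species-specific, summed over species, divided by the total ungapped 3'
#' UTR length summed over the species in that gene's alignment. Genes
#' without species-specific sites get rate 0.
#'
#' @param sites data.frame from [predict_target_sites()].
#' @param ss_mirnas character vector of species-specific miRNA gene ids.
#' @param utr_lengths data.frame with `gene_id`, `species`, `length`
#'   (ungapped), covering every target gene.
#' @return data.frame: `gene_id`, `n_ss_sites`, `total_utr_length`, `rate`,
#'   sorted by `gene_id`.
#' @export
emergence_rates <- function(sites, ss_mirnas, utr_lengths) {
  tot <- tapply(utr_lengths$length, utr_lengths$gene_id, sum)
  if (any(tot <= 0)) stop("zero total UTR length for a gene")
  ss <- sites[sites$mirna_gene %in% ss_mirnas, , drop = FALSE]
  cnt <- table(factor(ss$target_gene, levels = names(tot)))
  data.frame(
    gene_id = names(tot),
    n_ss_sites = as.integer(cnt),
    total_utr_length = as.numeric(tot),
    rate = as.integer(cnt) / as.numeric(tot),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Select the top fraction of genes by emergence rate
#'
#' Sorts by rate descending with ties broken by gene id ascending and takes
#' the ceiling of `fraction * N` genes, so the selection is deterministic
#' and stable under shuffling of the input records.
#'
#' @param records data.frame with `gene_id` and `rate` (from
#'   [emergence_rates()]); non-empty.
#' @param fraction in (0, 1); default 0.05 (top 5%).
#' @return character vector of selected gene ids.
#' @export
select_top_fraction <- function(records, fraction = 0.05) {
  if (nrow(records) == 0) stop("no records")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ord <- order(-records$rate, records$gene_id)
  records$gene_id[ord][seq_len(ceiling(fraction * nrow(records)))]
}

#' Total target-site counts per miRNA gene
#'
#' Sites summed over target genes and species; miRNA genes without any site
#' appear with count 0.
#'
#' @param sites data.frame from [predict_target_sites()].
#' @param mirna_genes character vector of all miRNA gene ids to report.
#' @return named integer vector of site counts.
#' @export
target_counts_per_mirna <- function(sites, mirna_genes) {
  cnt <- table(factor(sites$mirna_gene, levels = sort(unique(mirna_genes))))
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Binary species-by-pair target-pattern matrix for PCA
#'
#' Restricted to conserved miRNAs and target genes aligned in all species:
#' entry 1 when the species carries at least one site for the
#' (miRNA, gene) pair.
#'
#' @param sites data.frame from [predict_target_sites()].
#' @param conserved_mirnas miRNA gene ids present in all species.
#' @param universal_genes target gene ids aligned in all species.
#' @param species character vector of all species.
#' @return binary matrix, rows = species, columns = `mirna|gene` pairs.
#' @export
target_pattern_matrix <- function(sites, conserved_mirnas, universal_genes,
                                  species) {
  s <- sites[sites$mirna_gene %in% conserved_mirnas &
               sites$target_gene %in% universal_genes, , drop = FALSE]
  pairs <- sort(unique(paste(s$mirna_gene, s$target_gene, sep = "|")))
  m <- matrix(0L, length(species), length(pairs),
              dimnames = list(sort(species), pairs))
  if (nrow(s) > 0) {
    idx <- cbind(match(s$species, rownames(m)),
                 match(paste(s$mirna_gene, s$target_gene, sep = "|"), pairs))
    m[unique(idx)] <- 1L
  }
  m
}
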