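#' Load a study directory written by [write_synthetic_study()]
#'
#' Reads the standard-format inputs (per-species FASTA, BED6, newick,
#' aligned FASTA per gene, count TSVs, annotation) back into the in-memory
#' study layout, including the planted-truth tables when present.
#'
#' @param dir study directory.
#' @return list shaped like the output of [simulate_study()] (sequence and
#'   truth fields only as far as files provide them).
#' @export
load_study <- function(dir) {
  tree <- read_species_tree(file.path(dir, "species_tree.nwk"))
  tips <- tree$tip.label
  matures <- do.call(rbind, lapply(tips, function(sp) {
    s <- read_fasta(file.path(dir, paste0(sp, "_mature.fa")), "rna")
    data.frame(id = names(s), species = sp, sequence = unname(s),
               stringsAsFactors = FALSE)
  }))
  premirnas <- do.call(rbind, lapply(tips, function(sp) {
    s <- read_fasta(file.path(dir, paste0(sp, "_precursor.fa")), "rna")
    data.frame(id = names(s), species = sp, sequence = unname(s),
               stringsAsFactors = FALSE)
  }))
  aln_files <- sort(list.files(file.path(dir, "alignments"),
                               pattern = "\\.fa$", full.names = TRUE))
  alignments <- lapply(aln_files, function(f) read_alignment(f, tips)$aln)
  names(alignments) <- sub("\\.fa$", "", basename(aln_files))
  samples <- utils::read.table(file.path(dir, "samples.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  gl <- utils::read.table(file.path(dir, "gene_lengths.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  truth_dir <- file.path(dir, "truth")
  truth <- NULL
  if (dir.exists(truth_dir)) {
    truth <- list(
      conservation = utils::read.table(
        file.path(truth_dir, "conservation.tsv"), header = TRUE, sep = "\t",
        stringsAsFactors = FALSE),
      planted_sites = utils::read.table(
        file.path(truth_dir, "planted_sites.tsv"), header = TRUE, sep = "\t",
        stringsAsFactors = FALSE),
      repression_pairs = utils::read.table(
        file.path(truth_dir, "repression_pairs.tsv"), header = TRUE,
        sep = "\t", stringsAsFactors = FALSE)
    )
  }
  list(
    config = list(tree = tree),
    repertoires = list(matures = matures, premirnas = premirnas,
                       truth = truth),
    coordinates = list(bed = read_bed(file.path(dir, "premirnas.bed"))),
    utrs = list(alignments = alignments),
    expression = list(
      mirna_counts = read_expression_tsv(file.path(dir, "mirna_counts.tsv")),
      mrna_counts = read_expression_tsv(file.path(dir, "mrna_counts.tsv")),
      species_of_sample = stats::setNames(samples$species, samples$sample),
      gene_lengths = stats::setNames(as.numeric(gl$length), gl$gene_id)
    ),
    annotation = list(annotation = utils::read.table(
      file.path(dir, "annotation.tsv"), header = TRUE, sep = "\t",
      stringsAsFactors = FALSE))
  )
}

#' Build the miRNA catalog: families, genes, conservation, gain/loss
#'
#' Runs family construction, isomiR grouping, conservation classification,
#' the variability cross-table and per-gene Dollo gain/loss inference.
#'
#' @param matures data.frame with `id`, `species`, `sequence`.
#' @param tree species tree.
#' @param ... passed to [build_families()].
#' @return list with `matures` (annotated), `conservation`, `variability`
#'   (table + chi-square) and `gainloss` (per-gene data.frame).
#' @export
build_catalog <- function(matures, tree, ...) {
  fams <- assign_isomirs(build_families(matures, ...))
  cons <- classify_conservation(fams, tree)
  vt <- variability_table(cons, fams)
  vt$test <- if (all(rowSums(vt$table) > 0) && all(colSums(vt$table) > 0)) {
    chi2_2x2(vt$table, yates = TRUE)
  } else NULL
  gene_sp <- lapply(split(fams$species, fams$gene_id), unique)
  gl <- lapply(names(gene_sp), function(g) {
    pres <- stats::setNames(tree$tip.label %in% gene_sp[[g]], tree$tip.label)
    ev <- dollo_gain_loss(tree, pres)
    data.frame(gene_id = g, gain_branch = ev$gain_branch,
               loss_branches = paste(ev$loss_branches, collapse = ","),
               n_events = ev$n_events, stringsAsFactors = FALSE)
  })
  list(matures = fams, conservation = cons, variability = vt,
       gainloss = do.call(rbind, gl))
}

#' Conservation class of each pre-miRNA
#'
#' A precursor is `conserved` when any miRNA gene carried by its hairpin is
#' present in all species; otherwise `non-conserved` (the two-class
#' contrast used in the clustered-fraction comparison).
#'
#' @param premirnas data.frame with `id`, `species` and (optionally)
#'   `sequence` for matching precursors to matures.
#' @param catalog output of [build_catalog()].
#' @param tree species tree.
#' @return named character vector (`conserved` / `non-conserved`) per
#'   precursor id.
#' @export
premirna_classes <- function(premirnas, catalog, tree) {
  mat <- catalog$matures
  cons <- catalog$conservation
  gene_class <- stats::setNames(cons$class, cons$gene_id)
  gene_of_mature <- stats::setNames(mat$gene_id, mat$id)
  # precursor -> mature via the "<mature id>_pre" naming convention, with a
  # fall-back to matching the embedded mature sequence
  mature_of_pre <- function(i) {
    guess <- sub("_pre$", "", premirnas$id[i])
    hits <- names(gene_of_mature)[startsWith(names(gene_of_mature), guess)]
    hits <- hits[mat$species[match(hits, mat$id)] == premirnas$species[i]]
    if (length(hits) > 0) return(hits)
    if (!is.null(premirnas$sequence)) {
      sp_rows <- which(mat$species == premirnas$species[i])
      emb <- vapply(mat$sequence[sp_rows], function(s) {
        grepl(s, premirnas$sequence[i], fixed = TRUE)
      }, TRUE)
      return(mat$id[sp_rows][emb])
    }
    character(0)
  }
  cls <- vapply(seq_len(nrow(premirnas)), function(i) {
    genes <- unique(gene_of_mature[mature_of_pre(i)])
    if (length(genes) > 0 && any(gene_class[genes] == "conserved")) {
      "conserved"
    } else "non-conserved"
  }, "")
  stats::setNames(cls, premirnas$id)
}

#' Run the comparative analysis over a study
#'
#' Composes the whole workflow on an in-memory study (simulated or loaded):
#' catalog building, cluster detection and class comparisons, target-site
#' prediction with conservation calls and spatial statistics, expression
#' normalisation, PCA, miRNA-mRNA correlation (raw across individuals and
#' via phylogenetically independent contrasts across species), emergence
#' rates and GO enrichment of the top genes.
#'
#' @param study list from [simulate_study()] or [load_study()].
#' @param max_gap cluster chaining distance in bp (default 5000).
#' @param top_fraction emergence-rate selection fraction (default 0.05).
#' @return Nested list with components `catalog`, `clusters`, `targets`,
#'   `spatial`, `expression`, `correlation`, `emergence`.
#' @export
analyze_study <- function(study, max_gap = 5000, top_fraction = 0.05) {
  tree <- study$config$tree
  tips <- tree$tip.label

  catalog <- build_catalog(
    study$repertoires$matures[, c("id", "species", "sequence")], tree)
  cons <- catalog$conservation
  conserved_mirnas <- cons$gene_id[cons$class == "conserved"]
  ss_mirnas <- cons$gene_id[cons$class == "species-specific"]

  # genomic clusters
  cs <- detect_clusters(study$coordinates$bed, max_gap = max_gap)
  pre_cls <- premirna_classes(study$repertoires$premirnas, catalog, tree)
  cft <- clustered_fraction_test(pre_cls, cs)
  labelled <- label_clusters(cs, pre_cls)
  dens_a <- labelled$density[labelled$class_label == "conserved"]
  dens_b <- labelled$density[labelled$class_label == "non-conserved"]
  dens_test <- if (length(dens_a) >= 2 && length(dens_b) >= 2) {
    density_comparison(dens_a, dens_b)
  } else NULL
  clusters <- list(clusterset = cs, labelled = labelled,
                   fraction_test = cft, density_test = dens_test)

  # target sites
  sites <- predict_target_sites(
    study$utrs$alignments,
    catalog$matures[, c("gene_id", "species", "sequence")])
  sites <- call_site_conservation(sites, study$utrs$alignments)

  # spatial statistics: all sites vs conserved sites, and long/short UTRs
  slope_of <- function(pos) {
    if (length(unique(pos)) < 2) return(NA_real_)
    pr <- spatial_profile(pos)
    density_slope(pr$grid, pr$density)$slope
  }
  mean_len <- vapply(study$utrs$alignments, function(a) {
    mean(nchar(gsub("-", "", a, fixed = TRUE)))
  }, 0)
  ls_split <- split_by_length(mean_len)
  co <- sites[sites$conserved_site, , drop = FALSE]
  spatial <- list(
    slope_all = slope_of(sites$rel_pos),
    slope_conserved = slope_of(co$rel_pos),
    slope_all_long = slope_of(sites$rel_pos[sites$target_gene %in%
                                              ls_split$long]),
    slope_all_short = slope_of(sites$rel_pos[sites$target_gene %in%
                                               ls_split$short]),
    slope_conserved_long = slope_of(co$rel_pos[co$target_gene %in%
                                                 ls_split$long]),
    slope_conserved_short = slope_of(co$rel_pos[co$target_gene %in%
                                                  ls_split$short])
  )

  # per-miRNA target counts by conservation class
  counts <- target_counts_per_mirna(sites, cons$gene_id)
  cnt_test <- if (length(conserved_mirnas) >= 1 && length(ss_mirnas) >= 1) {
    mann_whitney_u(counts[conserved_mirnas], counts[ss_mirnas],
                   alternative = "greater")
  } else NULL

  # expression: normalisation and PCA
  rpm <- rpm_normalize(study$expression$mirna_counts)
  tpm <- tpm_normalize(study$expression$mrna_counts,
                       study$expression$gene_lengths)
  pca_mirna <- pca(log2(rpm + 1))
  pca_mrna <- pca(log2(tpm + 1))
  universal_genes <- names(study$utrs$alignments)[vapply(
    study$utrs$alignments, function(a) all(tips %in% names(a)), TRUE)]
  tpm_mat <- target_pattern_matrix(sites, conserved_mirnas,
                                   universal_genes, tips)
  pca_targets <- if (ncol(tpm_mat) >= 1) pca(t(tpm_mat)) else NULL

  # functional pairs: sites conserved in every species ("predicted in all")
  pairs <- unique(data.frame(mirna_gene = co$mirna_gene,
                             target_gene = co$target_gene,
                             stringsAsFactors = FALSE))
  correlation <- NULL
  if (nrow(pairs) > 0) {
    pc <- pair_correlations(rpm, tpm, pairs)
    sb <- if (sum(!is.na(pc$r) & pc$r != 0) >= 2) sign_bias_test(pc$r) else NULL
    sm <- species_mean_expression(rpm, study$expression$species_of_sample)
    gm <- species_mean_expression(tpm, study$expression$species_of_sample)
    pic_r <- vapply(seq_len(nrow(pc)), function(i) {
      if (!pc$mirna_gene[i] %in% rownames(sm) ||
          !pc$target_gene[i] %in% rownames(gm)) return(NA_real_)
      cx <- pic_contrasts(tree, sm[pc$mirna_gene[i], ])
      cy <- pic_contrasts(tree, gm[pc$target_gene[i], ])
      pic_correlation(cx$contrast, cy$contrast)
    }, 0)
    sb_pic <- if (sum(!is.na(pic_r) & pic_r != 0) >= 2)
      sign_bias_test(pic_r) else NULL
    correlation <- list(pairs = pc, pic_r = pic_r,
                        sign_bias = sb, sign_bias_pic = sb_pic)
  }

  # emergence rates and GO enrichment of the top fraction
  utr_lengths <- do.call(rbind, lapply(names(study$utrs$alignments),
                                       function(g) {
    a <- study$utrs$alignments[[g]]
    data.frame(gene_id = g, species = names(a),
               length = nchar(gsub("-", "", a, fixed = TRUE)),
               stringsAsFactors = FALSE)
  }))
  em <- emergence_rates(sites, ss_mirnas, utr_lengths)
  top <- select_top_fraction(em, top_fraction)
  enrich <- if (!is.null(study$annotation)) {
    go_enrichment(top, em$gene_id, study$annotation$annotation)
  } else NULL

  list(
    catalog = catalog,
    clusters = clusters,
    targets = list(sites = sites, counts_per_mirna = counts,
                   count_test = cnt_test),
    spatial = spatial,
    expression = list(rpm = rpm, tpm = tpm, pca_mirna = pca_mirna,
                      pca_mrna = pca_mrna, pca_targets = pca_targets),
    correlation = correlation,
    emergence = list(rates = em, top_genes = top, enrichment = enrich)
  )
}
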