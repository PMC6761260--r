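test_that("simulation is deterministic given a seed and config", {
  cfg <- sim_config(n_families = 15, n_genes = 12,
                    individuals_per_species = 2, rng_seed = 77)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$repertoires$matures, b$repertoires$matures)
  expect_identical(a$coordinates$bed, b$coordinates$bed)
  expect_identical(a$utrs$alignments, b$utrs$alignments)
  expect_identical(a$expression$mirna_counts, b$expression$mirna_counts)
})

test_that("degenerate rate settings force the expected presence patterns", {
  # no losses, everything ancestral: every family in all 8 species
  cfg <- sim_config(n_families = 12, p_root_family = 1, loss_rate = 0,
                    seed_mut_prob = c(root = 0, novel = 0),
                    isomir_prob = c(root = 0, tip = 0),
                    n_genes = 5, individuals_per_species = 2, rng_seed = 3)
  rep <- simulate_repertoires(cfg)
  expect_true(all(rep$truth$conservation$class == "conserved"))
  expect_equal(nrow(rep$matures), 12 * 8)

  # no ancestral families, no losses: presence = clade below the gain branch
  cfg2 <- sim_config(n_families = 30, p_root_family = 0, loss_rate = 0,
                     seed_mut_prob = c(root = 0, novel = 0),
                     isomir_prob = c(root = 0, tip = 0),
                     n_genes = 5, individuals_per_species = 2, rng_seed = 4)
  rep2 <- simulate_repertoires(cfg2)
  tips <- cfg2$tree$tip.label
  term <- rep2$truth$family_origin_branch[
    rep2$truth$family_origin_branch %in% tips]
  for (fam in names(term)) {
    sp <- unique(rep2$matures$species[rep2$matures$true_family == fam])
    expect_equal(sp, unname(term[fam]))  # terminal gain: exactly 1 species
  }
})

test_that("conservation truth equals presence recomputed from matures", {
  st <- small_study()
  m <- st$repertoires$matures
  tru <- st$repertoires$truth$conservation
  n_sp <- vapply(split(m$species, m$gene_id),
                 function(s) length(unique(s)), 0L)
  expect_equal(tru$n_species[match(names(n_sp), tru$gene_id)], unname(n_sp))
  # classes partition the genes
  expect_equal(sum(table(tru$class)), nrow(tru))
})

test_that("coordinate simulation plants recoverable clusters", {
  # cluster_prob 0: no two precursors within 5 kb anywhere
  st <- small_study()
  cfg0 <- sim_config(n_families = 20, n_genes = 5,
                     cluster_prob = c(root = 0, tip = 0),
                     individuals_per_species = 2, rng_seed = 5)
  rep0 <- simulate_repertoires(cfg0)
  co0 <- simulate_coordinates(rep0, cfg0)
  expect_equal(nrow(detect_clusters(co0$bed)$clusters), 0)
  expect_equal(length(co0$planted_clusters), 0)

  # cluster_prob 1 on one scaffold: a single chain, all gaps < 5 kb
  cfg1 <- sim_config(n_families = 10, n_genes = 5, n_scaffolds = 1,
                     p_root_family = 1, loss_rate = 0,
                     cluster_prob = c(root = 1, tip = 1),
                     individuals_per_species = 2, rng_seed = 6)
  rep1 <- simulate_repertoires(cfg1)
  co1 <- simulate_coordinates(rep1, cfg1)
  per_species <- split(co1$bed, sub("_.*$", "", co1$bed$name))
  for (b in per_species) {
    cs <- detect_clusters(b)
    expect_equal(nrow(cs$clusters), 1)
    expect_equal(cs$clusters$n, nrow(b))
  }

  # planted gaps < 4 kb, isolation >= 100 kb: exact recovery at 5 kb
  got <- membership_groups(detect_clusters(st$coordinates$bed))
  expect_true(same_group_sets(got, st$coordinates$planted_clusters))
})

test_that("planted UTR sites are exactly recoverable with their types", {
  st <- small_study()
  pl <- st$utrs$planted_sites
  tips <- st$config$tree$tip.label
  expect_gt(nrow(pl), 0)
  for (i in seq_len(nrow(pl))) {
    sp_list <- if (is.na(pl$species[i])) tips else pl$species[i]
    mseq <- st$repertoires$matures$sequence[
      st$repertoires$matures$gene_id == pl$mirna_gene[i]][1]
    for (sp in sp_list) {
      utr <- gsub("-", "", st$utrs$alignments[[pl$target_gene[i]]][[sp]],
                  fixed = TRUE)
      hits <- find_seed_sites(utr, mseq)
      expect_true(pl$site_type[i] %in% hits$site_type,
                  label = sprintf("site %d (%s in %s)", i, pl$site_type[i], sp))
    }
  }
  # conserved planted sites follow the 5'-skewed Beta(1,3): mean rel pos ~.25
  cons <- pl[pl$conserved, ]
  if (nrow(cons) >= 20) {
    g_len <- vapply(st$utrs$alignments[cons$target_gene],
                    function(a) nchar(gsub("-", "", a[[1]], fixed = TRUE)), 0)
    expect_lt(mean(cons$start / g_len), 0.35)
  }
})

test_that("expression coupling produces negative miRNA-mRNA correlations", {
  # decoupled generator: correlations centre on zero
  cfg0 <- sim_config(n_families = 30, n_genes = 40, repression_gamma = 0,
                     individuals_per_species = 4, rng_seed = 8)
  st0 <- simulate_study(cfg0)
  pc0 <- pair_correlations(rpm_normalize(st0$expression$mirna_counts),
                           tpm_normalize(st0$expression$mrna_counts,
                                         st0$expression$gene_lengths),
                           st0$utrs$repression_pairs)
  expect_lt(abs(mean(pc0$r, na.rm = TRUE)), 0.15)

  # strong coupling, low noise: planted pairs overwhelmingly negative
  cfg1 <- sim_config(n_families = 30, n_genes = 40, repression_gamma = 1,
                     noise_sigma = 0.05, individuals_per_species = 4,
                     rng_seed = 8)
  st1 <- simulate_study(cfg1)
  pc1 <- pair_correlations(rpm_normalize(st1$expression$mirna_counts),
                           tpm_normalize(st1$expression$mrna_counts,
                                         st1$expression$gene_lengths),
                           st1$utrs$repression_pairs)
  expect_gt(mean(pc1$r < 0, na.rm = TRUE), 0.9)

  # ancestral families are expressed above lineage-specific ones
  st <- small_study()
  rpm <- rpm_normalize(st$expression$mirna_counts)
  root <- names(which(st$repertoires$truth$gene_origin_root))
  tipg <- names(which(!st$repertoires$truth$gene_origin_root))
  mw <- mann_whitney_u(rowMeans(rpm[root, , drop = FALSE]),
                       rowMeans(rpm[tipg, , drop = FALSE]),
                       alternative = "greater")
  expect_lt(mw$p_value, 0.05)
})

test_that("written studies load back with identical analysis inputs", {
  st <- small_study()
  d <- withr::local_tempdir()
  write_synthetic_study(st, d)
  st2 <- load_study(d)
  expect_equal(sort(st2$repertoires$matures$id),
               sort(st$repertoires$matures$id))
  expect_equal(st2$coordinates$bed$start[order(st2$coordinates$bed$name)],
               st$coordinates$bed$start[order(st$coordinates$bed$name)])
  expect_identical(st2$utrs$alignments[["g001"]],
                   st$utrs$alignments[["g001"]])
  expect_equal(st2$expression$mirna_counts, st$expression$mirna_counts)
  expect_equal(st2$expression$species_of_sample,
               st$expression$species_of_sample)
})
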