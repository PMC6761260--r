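MIR <- "UGGAAUGUAAAGAAGUAUGUAU"  # a canonical ~22-nt mature

test_that("site match strings derive from the seed by reverse complement", {
  ss <- site_strings(MIR)
  expect_equal(unname(ss["6mer"]), "CAUUCC")
  expect_equal(unname(ss["7mer-m8"]), "ACAUUCC")
  expect_equal(unname(ss["7mer-A1"]), "CAUUCCA")
  expect_equal(unname(ss["8mer"]), "ACAUUCCA")
  expect_equal(unname(site_strings(strrep("A", 22))["6mer"]), "UUUUUU")
  # the four strings are mutually consistent by construction
  expect_equal(unname(ss["8mer"]), paste0(ss["7mer-m8"], "A"))
  expect_equal(unname(ss["8mer"]),
               paste0(substr(ss["7mer-m8"], 1, 1), ss["7mer-A1"]))
  expect_error(site_strings("ACGUACG"), "shorter")
})

test_that("seed-site scanning reports the strongest type per locus", {
  s1 <- find_seed_sites("GGACAUUCCAGG", MIR)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$site_type, "8mer")
  expect_equal(s1$start, 2)
  expect_equal(s1$length, 8)
  s2 <- find_seed_sites("GGACAUUCCGGG", MIR)
  expect_equal(s2$site_type, "7mer-m8")
  expect_equal(s2$start, 2)
  expect_equal(nrow(find_seed_sites("GGGGGGGGGGGG", MIR)), 0)
  expect_equal(nrow(find_seed_sites("", MIR)), 0)
})

test_that("seed-site scanning equals the brute-force substring oracle", {
  set.seed(31)
  mirnas <- replicate(50, paste(sample(c("A", "C", "G", "U"), 22,
                                       replace = TRUE), collapse = ""))
  for (rep in 1:6) {
    utr <- paste(sample(c("A", "C", "G", "U"), 10000, replace = TRUE),
                 collapse = "")
    for (m in mirnas[sample(50, 8)]) {
      got <- find_seed_sites(utr, m)
      got <- got[order(got$start, got$site_type), , drop = FALSE]
      rownames(got) <- NULL
      expect_equal(got, oracle_seed_sites(utr, m))
    }
  }
  # homopolymer seeds produce self-overlapping loci; all must be reported
  polyu_mir <- paste0("G", strrep("A", 21))   # seed AAAAAAA -> 6mer UUUUUU
  utr <- "GGUUUUUUUUCC"
  got <- find_seed_sites(utr, polyu_mir)
  expect_equal(got, oracle_seed_sites(utr, polyu_mir))
  expect_gt(nrow(got), 1)
})

test_that("relative position maps the site midpoint into [0,1]", {
  expect_equal(relative_position(0, 7, 1000), 0.003, tolerance = 2e-3)
  expect_equal(relative_position(497, 6, 1000), 0.5, tolerance = 1e-3)
  expect_equal(relative_position(0, 7, 7), 0.5)   # single placement
  expect_error(relative_position(0, 8, 7), "shorter")
})

test_that("site conservation needs an overlapping site in every species", {
  tips <- cichlid_tree()$tip.label
  utr <- paste0("GG", "ACAUUCCA", strrep("CG", 20))
  aln <- list(g1 = stats::setNames(rep(utr, 8), tips))
  catalog <- data.frame(gene_id = "mirX", species = tips, sequence = MIR)
  sites <- predict_target_sites(aln, catalog)
  sites <- call_site_conservation(sites, aln)
  expect_equal(nrow(sites), 8)
  expect_true(all(sites$conserved_site))
  # drop one species' miRNA: site present in 7 of 8 -> not conserved
  sites7 <- predict_target_sites(aln, catalog[-1, ])
  sites7 <- call_site_conservation(sites7, aln)
  expect_false(any(sites7$conserved_site))
  # same miRNA at disjoint columns in one species -> not conserved
  shifted <- paste0(strrep("CG", 20), "ACAUUCCA", "GG")
  aln2 <- list(g1 = stats::setNames(c(shifted, rep(utr, 7)), tips))
  sites2 <- call_site_conservation(predict_target_sites(aln2, catalog), aln2)
  expect_false(any(sites2$conserved_site))
})

test_that("density profile integrates to ~1 and respects symmetry", {
  set.seed(13)
  x <- rbeta(4000, 5, 5)  # interior-massed
  pr <- spatial_profile(x)
  integral <- sum(diff(pr$grid) * (head(pr$density, -1) + pr$density[-1]) / 2)
  expect_equal(integral, 1, tolerance = 0.02)
  # symmetric positions give a symmetric density
  xs <- c(x, 1 - x)
  ps <- spatial_profile(xs)
  expect_lt(max(abs(ps$density - rev(ps$density))), 1e-10)
  # uniform draws: flat near 1 away from the edges
  u <- runif(10000)
  pu <- spatial_profile(u)
  inner <- pu$grid >= 0.2 & pu$grid <= 0.8
  expect_lt(max(abs(pu$density[inner] - 1)), 0.1)
  expect_error(spatial_profile(rep(0.4, 10)), "distinct")
})

test_that("density slope is exact on affine data and signs skewness", {
  g <- seq(0, 1, length.out = 512)
  expect_equal(density_slope(g, rep(2, 512))$slope, 0, tolerance = 1e-12)
  r <- density_slope(g, 2 - 2 * g)
  expect_equal(r$slope, -2, tolerance = 1e-10)
  expect_equal(r$intercept, 2, tolerance = 1e-10)
  set.seed(17)
  pr <- spatial_profile(rbeta(5000, 1, 3))
  expect_lt(density_slope(pr$grid, pr$density)$slope, 0)
  expect_error(density_slope(c(0, 1), c(1, 1)), "3 grid points")
})

test_that("UTR length split is strict-greater-than-median", {
  expect_equal(split_by_length(c(a = 100, b = 200, c = 300)),
               list(long = "c", short = c("a", "b")))
  expect_equal(split_by_length(c(a = 5, b = 5))$long, character(0))
  expect_equal(split_by_length(c(a = 1, b = 2, c = 3, d = 4))$long,
               c("c", "d"))
})

test_that("emergence rates are species-specific sites per summed UTR nt", {
  sites <- data.frame(
    target_gene = rep("g1", 5), species = c("s1", "s1", "s2", "s2", "s1"),
    mirna_gene = c("ss1", "ss1", "ss2", "ss2", "cons1"))
  ul <- data.frame(gene_id = rep(c("g1", "g2"), each = 2),
                   species = rep(c("s1", "s2"), 2),
                   length = c(1200, 800, 500, 500))
  em <- emergence_rates(sites, c("ss1", "ss2"), ul)
  expect_equal(em$rate[em$gene_id == "g1"], 4 / 2000)
  expect_equal(em$rate[em$gene_id == "g2"], 0)
  # no species-specific miRNAs: all rates 0
  em0 <- emergence_rates(sites, character(0), ul)
  expect_true(all(em0$rate == 0))
  # doubling UTRs with the same sites halves the rates
  ul2 <- ul
  ul2$length <- ul$length * 2
  expect_equal(emergence_rates(sites, c("ss1", "ss2"), ul2)$rate, em$rate / 2)
})

test_that("top-fraction selection is deterministic under ties and shuffles", {
  rec <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    rate = c(rep(0.5, 3), runif(97, 0, 0.4)))
  expect_equal(length(select_top_fraction(rec, 0.05)), 5)
  rec101 <- rbind(rec, data.frame(gene_id = "g101", rate = 0.01))
  expect_equal(length(select_top_fraction(rec101, 0.05)), 6)
  # tie at the cut resolved by gene id; stable under row shuffling
  tie <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    rate = rep(c(1, 0.5), each = 20))
  top <- select_top_fraction(tie, 0.05)
  expect_equal(top, c("g01", "g02"))
  set.seed(2)
  expect_equal(select_top_fraction(tie[sample(40), ], 0.05), top)
})

test_that("per-miRNA counts include zeros and the pattern matrix is binary", {
  sites <- data.frame(target_gene = c("g1", "g1", "g2"),
                      species = c("s1", "s2", "s1"),
                      mirna_gene = c("mA", "mA", "mB"))
  cnt <- target_counts_per_mirna(sites, c("mA", "mB", "mC"))
  expect_equal(unname(cnt[c("mA", "mB", "mC")]), c(2L, 1L, 0L))
  m <- target_pattern_matrix(sites, c("mA", "mB"), c("g1", "g2"),
                             c("s1", "s2"))
  expect_true(all(m %in% 0:1))
  expect_equal(m["s1", "mA|g1"], 1L)
  expect_equal(m["s2", "mB|g2"], 0L)
})
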