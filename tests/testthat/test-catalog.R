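test_that("local alignment scores, identities and degenerate cases", {
  r <- local_align_score("ACGU", "ACGU")
  expect_equal(r$score, 20)
  expect_equal(r$identity, 1.0)
  r2 <- local_align_score("AAAA", "CCCC")
  expect_equal(r2$score, 0)
  r3 <- local_align_score("ACGUACGU", "GUAC")
  expect_equal(r3$score, 20)
  expect_equal(r3$aligned_length, 4)
  expect_equal(r3$identity, 1.0)
  expect_error(local_align_score("", "ACGU"), "empty")
})

test_that("family construction is single-linkage and order-invariant", {
  # two identical sequences -> one family
  m <- data.frame(id = c("x", "y"), species = c("s1", "s2"),
                  sequence = rep("UGAGGUAGUAGGUUGUAUAGUU", 2))
  expect_equal(length(unique(build_families(m)$family_id)), 1)

  # chain a-b, b-c without a-c still forms one family (single linkage):
  # b differs from a at 5 spread positions, c from b at 5 more
  a <- "UGAGGUAGUAGGUUGUAUAGUU"
  b <- a; for (p in c(3, 7, 11, 15, 19)) substr(b, p, p) <-
    chartr("ACGU", "CAUG", substr(b, p, p))
  c_ <- b; for (p in c(4, 8, 12, 16, 20)) substr(c_, p, p) <-
    chartr("ACGU", "CAUG", substr(c_, p, p))
  expect_gte(local_align_score(a, b)$identity, 0.75)
  expect_gte(local_align_score(b, c_)$identity, 0.75)
  expect_lt(local_align_score(a, c_)$identity, 0.75)
  m3 <- data.frame(id = c("a", "b", "c"), species = "s1",
                   sequence = c(a, b, c_))
  f3 <- build_families(m3)
  expect_equal(length(unique(f3$family_id)), 1)
  expect_equal(unique(f3$family_id), "a")  # smallest member id

  # dissimilar sequences stay singletons
  m4 <- data.frame(id = c("p", "q", "r"), species = "s1",
                   sequence = c(strrep("A", 22), strrep("C", 22),
                                strrep("G", 22)))
  expect_equal(length(unique(build_families(m4)$family_id)), 3)

  # input order does not change the id -> family map
  set.seed(1)
  mall <- rbind(m3, m4)
  shuffled <- mall[sample(nrow(mall)), ]
  f_ref <- build_families(mall)
  f_shuf <- build_families(shuffled)
  expect_equal(f_shuf$family_id[match(f_ref$id, f_shuf$id)], f_ref$family_id)
})

test_that("isomiR grouping splits families by seed and flags variability", {
  base <- "UGAGGUAGUAGGUUGUAUAGUU"
  trimmed <- substr(base, 1, 21)                    # 3' length variant
  seedmut <- base; substr(seedmut, 4, 4) <- "C"     # seed position differs
  m <- data.frame(id = c("m1", "m2", "m3"), species = c("s1", "s1", "s2"),
                  sequence = c(base, trimmed, seedmut))
  f <- assign_isomirs(build_families(m))
  # same family, same seed, different 3' end: one variable gene
  expect_equal(f$gene_id[1], f$gene_id[2])
  expect_true(all(f$variable[1:2]))
  # seed mismatch: separate gene in the same family
  expect_equal(length(unique(f$family_id)), 1)
  expect_false(f$gene_id[3] == f$gene_id[1])
  expect_false(f$variable[3])                       # singleton gene
})

test_that("conservation classes partition genes by species breadth", {
  tr <- cichlid_tree()
  tips <- tr$tip.label
  m <- rbind(
    data.frame(gene_id = "gA", species = tips),            # all 8
    data.frame(gene_id = "gB", species = tips[1]),         # exactly 1
    data.frame(gene_id = "gC", species = tips[1:3])        # 3 of 8
  )
  cl <- classify_conservation(m, tr)
  expect_equal(cl$class[cl$gene_id == "gA"], "conserved")
  expect_equal(cl$class[cl$gene_id == "gB"], "species-specific")
  expect_equal(cl$class[cl$gene_id == "gC"], "non-conserved")
  expect_equal(sum(table(cl$class)), nrow(cl))
  expect_error(classify_conservation(
    data.frame(gene_id = "g", species = "Mars"), tr), "not on the tree")
})

test_that("known/novel annotation uses identity over the shorter sequence", {
  ref <- c(ref1 = "UGAGGUAGUAGGUUGUAUAGUU")
  exact <- data.frame(gene_id = "g1", sequence = unname(ref))
  expect_true(annotate_known(exact, ref)$known)
  far <- data.frame(gene_id = "g2", sequence = strrep("AC", 11))
  expect_false(annotate_known(far, ref)$known)
  # identity 17/19 = 0.895 < 0.9 -> novel (strict threshold);
  # 18/19 = 0.947 -> known
  short2 <- substr(ref, 1, 19)
  substr(short2, 9, 9) <- "C"
  one_sub <- short2
  substr(short2, 14, 14) <- "C"
  expect_true(annotate_known(data.frame(gene_id = "g3", sequence = one_sub),
                             ref)$known)
  expect_false(annotate_known(data.frame(gene_id = "g4", sequence = short2),
                              ref)$known)
})

test_that("Dollo gain/loss matches exhaustive single-gain enumeration", {
  tr <- tree_from_text("((A:1,B:1):1,(C:1,D:1):1);")
  # present everywhere: root gain, no losses
  r <- dollo_gain_loss(tr, c(A = TRUE, B = TRUE, C = TRUE, D = TRUE))
  expect_equal(r$gain_branch, "root")
  expect_equal(r$n_events, 1)
  # single carrier: terminal gain
  r1 <- dollo_gain_loss(tr, c(A = FALSE, B = FALSE, C = TRUE, D = FALSE))
  expect_equal(r1$gain_branch, "C")
  expect_equal(r1$n_events, 1)
  # {A,B,D}: root gain with one loss on C's branch
  r2 <- dollo_gain_loss(tr, c(A = TRUE, B = TRUE, C = FALSE, D = TRUE))
  expect_equal(r2$gain_branch, "root")
  expect_equal(r2$loss_branches, "C")
  expect_equal(r2$n_events, 2)
  expect_error(dollo_gain_loss(tr, c(A = FALSE, B = FALSE, C = FALSE,
                                     D = FALSE)), "absent")

  # brute force over all presence patterns on random trees up to 6 tips
  set.seed(9)
  for (n in 4:6) {
    tr_r <- ape::rtree(n)
    tr_r$edge.length <- abs(tr_r$edge.length) + 0.1
    tips <- tr_r$tip.label
    for (mask in 1:(2^n - 1)) {
      pres <- stats::setNames(bitwAnd(mask, 2^(0:(n - 1))) > 0, tips)
      got <- dollo_gain_loss(tr_r, pres)
      want <- oracle_dollo(tr_r, pres)
      expect_equal(got$n_events, want$events)
      expect_equal(got$gain_branch, branch_label(tr_r, want$node))
    }
  }
})

test_that("variability cross-table reports counts and row percentages", {
  cl <- data.frame(
    gene_id = c(sprintf("c%d", 1:5), sprintf("s%d", 1:4)),
    class = c(rep("conserved", 5), rep("species-specific", 4)))
  m <- data.frame(gene_id = cl$gene_id,
                  variable = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                               TRUE, FALSE, FALSE, FALSE))
  vt <- variability_table(cl, m)
  expect_equal(vt$table["conserved", "variable"], 2)
  expect_equal(vt$table["species-specific", "invariant"], 3)
  expect_equal(unname(vt$percent_variable["conserved"]), 40.0)
  # an empty class yields NA, not 0
  vt2 <- variability_table(cl[1:5, , drop = FALSE], m[1:5, , drop = FALSE])
  expect_true(is.na(vt2$percent_variable["species-specific"]))
})
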