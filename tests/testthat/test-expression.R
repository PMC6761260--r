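test_that("TPM divides by length then scales columns to one million", {
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("f1", "f2"), "s1"))
  tpm <- tpm_normalize(counts, c(f1 = 1000, f2 = 500))
  expect_equal(unname(tpm[, 1]), c(333333.33, 666666.67), tolerance = 1e-6)
  # equal counts and lengths: uniform 1e6/n
  eq <- matrix(5, 4, 2, dimnames = list(letters[1:4], c("s1", "s2")))
  expect_true(all(abs(tpm_normalize(eq, stats::setNames(rep(100, 4),
                                                        letters[1:4])) -
                        2.5e5) < 1e-9))
  set.seed(8)
  m <- matrix(rpois(60, 20), 6, 10,
              dimnames = list(letters[1:6], paste0("s", 1:10)))
  lens <- stats::setNames(sample(200:2000, 6), letters[1:6])
  expect_equal(unname(colSums(tpm_normalize(m, lens))), rep(1e6, 10),
               tolerance = 1e-6)
  expect_error(tpm_normalize(m, stats::setNames(c(0, lens[-1]), letters[1:6])),
               "length")
  m0 <- m
  m0[, 3] <- 0
  expect_error(tpm_normalize(m0, lens), "s3")
})

test_that("RPM scales columns to one million and is scale-invariant", {
  one <- matrix(7, 1, 1, dimnames = list("f", "s"))
  expect_equal(unname(rpm_normalize(one)[1, 1]), 1e6)
  two <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(unname(rpm_normalize(two)[, 1]), c(250000, 750000))
  set.seed(8)
  m <- matrix(rpois(40, 30), 4, 10,
              dimnames = list(letters[1:4], paste0("s", 1:10)))
  expect_equal(unname(colSums(rpm_normalize(m))), rep(1e6, 10),
               tolerance = 1e-6)
  m2 <- m
  m2[, 1] <- m[, 1] * 17
  expect_equal(rpm_normalize(m2), rpm_normalize(m))
})

test_that("pair correlations follow Pearson on shared samples", {
  samples <- paste0("s", 1:4)
  mi <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("mA", samples))
  mr <- rbind(gX = c(2, 1, 4, 3), gY = 4 - c(1, 2, 3, 4), gZ = rep(2, 4))
  colnames(mr) <- samples
  pairs <- data.frame(mirna_gene = "mA", target_gene = c("gX", "gY", "gZ"))
  pc <- pair_correlations(mi, mr, pairs, transform = "none")
  expect_equal(pc$r[pc$target_gene == "gX"], 0.6, tolerance = 1e-12)
  expect_equal(pc$r[pc$target_gene == "gY"], -1, tolerance = 1e-12)
  expect_true(is.na(pc$r[pc$target_gene == "gZ"]))
  expect_error(pair_correlations(mi[, 1:2, drop = FALSE],
                                 mr[, 1:2, drop = FALSE], pairs),
               "3 shared")
})

test_that("independent contrasts match closed forms and hand pruning", {
  tr2 <- tree_from_text("(A:1,B:1);")
  pc <- pic_contrasts(tr2, c(A = 4, B = 2))
  expect_equal(pc$contrast, (4 - 2) / sqrt(2), tolerance = 1e-12)
  expect_equal(pc$variance, 2)
  # equal tip values: all contrasts zero
  tr <- cichlid_tree()
  x <- stats::setNames(rep(3.3, 8), tr$tip.label)
  expect_true(all(pic_contrasts(tr, x)$contrast == 0))
  # three-tip hand pruning: node value 2, extended branch 1.5
  tr3 <- tree_from_text("((A:1,B:1):1,C:2);")
  pc3 <- pic_contrasts(tr3, c(A = 1, B = 3, C = 10))
  expect_equal(sort(round(pc3$contrast, 4)), c(-4.2762, -1.4142))
  expect_setequal(round(pc3$variance, 6), c(2, 3.5))
  expect_error(pic_contrasts(tr3, c(A = 1, B = 3)), "missing tip")
  tr0 <- tr3
  tr0$edge.length[1] <- 0
  expect_error(pic_contrasts(tr0, c(A = 1, B = 3, C = 10)), "zero branch")
})

test_that("standardized contrasts have unit variance under Brownian motion", {
  # independent Brownian simulation by direct tree traversal
  tr <- cichlid_tree()
  n_tip <- length(tr$tip.label)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  blen <- stats::setNames(tr$edge.length, tr$edge[, 2])
  sim_bm <- function() {
    x <- numeric(n_tip + tr$Nnode)
    walk <- function(nd) {
      for (ch in kids[[as.character(nd)]]) {
        x[ch] <<- x[nd] + rnorm(1, 0, sqrt(blen[[as.character(ch)]]))
        if (ch > n_tip) walk(ch)
      }
    }
    walk(n_tip + 1)
    stats::setNames(x[1:n_tip], tr$tip.label)
  }
  set.seed(99)
  reps <- t(replicate(3000, pic_contrasts(tr, sim_bm())$contrast))
  v <- apply(reps, 2, var)
  expect_true(all(v > 0.9 & v < 1.1))
})

test_that("contrast correlation is through the origin and star-consistent", {
  x <- c(1, -2, 3)
  expect_equal(pic_correlation(x, 2 * x), 1)
  expect_equal(pic_correlation(x, -x), -1)
  expect_equal(pic_correlation(c(1, 0), c(0, 2)), 0)
  expect_true(is.na(pic_correlation(c(0, 0), c(1, 2))))
  # near-star symmetric 4-tip tree: contrast correlation ~ Pearson of tips
  tr <- tree_from_text("((A:1,B:1):0.0000000001,(C:1,D:1):0.0000000001);")
  set.seed(12)
  for (rep in 1:5) {
    xv <- stats::setNames(rnorm(4), tr$tip.label)
    yv <- stats::setNames(rnorm(4), tr$tip.label)
    r_pic <- pic_correlation(pic_contrasts(tr, xv)$contrast,
                             pic_contrasts(tr, yv)$contrast)
    expect_equal(r_pic, cor(xv, yv), tolerance = 1e-6)
  }
  # two tips: both correlations are a sign
  tr2 <- tree_from_text("(A:1,B:1);")
  xv <- c(A = 1, B = 5)
  yv <- c(A = 2, B = 0.5)
  expect_equal(pic_correlation(pic_contrasts(tr2, xv)$contrast,
                               pic_contrasts(tr2, yv)$contrast),
               cor(xv, yv), tolerance = 1e-9)
})

test_that("sign-bias test is an uncorrected 50:50 goodness of fit", {
  r <- sign_bias_test(c(rep(-0.2, 60), rep(0.3, 40)))
  expect_equal(r$n_negative, 60)
  expect_equal(r$test$statistic, 4.0)
  r2 <- sign_bias_test(c(-0.1, 0.1, -0.5, 0.5))
  expect_equal(r2$test$statistic, 0)
  expect_equal(r2$test$p_value, 1)
  r3 <- sign_bias_test(rep(-0.4, 20))
  expect_equal(r3$test$statistic, 20)
  # NAs and zeros are excluded from the counts
  r4 <- sign_bias_test(c(-1, 1, 0, NA, -0.5))
  expect_equal(r4$n_negative + r4$n_positive, 3)
})

test_that("species means average log2(x+1) within species", {
  expr <- matrix(c(3, 1, 7, 1), 1, 4,
                 dimnames = list("f", c("a1", "a2", "b1", "b2")))
  sm <- species_mean_expression(expr, c(a1 = "A", a2 = "A",
                                        b1 = "B", b2 = "B"))
  expect_equal(sm["f", "A"], mean(log2(c(3, 1) + 1)))
  expect_equal(sm["f", "B"], mean(log2(c(7, 1) + 1)))
})
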