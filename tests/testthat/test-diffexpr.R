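# Size factors, dispersion estimation, NB Wald test, BH adjustment.

mk_counts <- function(k, conditions = rep(c("A", "B"), each = 3),
                      kind = "gene") {
  colnames(k) <- paste0("s", seq_len(ncol(k)))
  rownames(k) <- paste0("f", seq_len(nrow(k)))
  count_matrix(k, data.frame(sample = colnames(k), condition = conditions,
                             replicate = ave(seq_len(ncol(k)), conditions,
                                             FUN = seq_along)),
               kind)
}

test_that("bh_adjust implements the step-up definition", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(10)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  # NA handling matches stats::p.adjust.
  p <- c(0.01, NA, 0.5, 0.02)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("size factors satisfy the forced examples and the ratio oracle", {
  k <- matrix(rep(c(10, 40, 200, 1000), 6), 4, 6)
  expect_equal(unname(size_factors(mk_counts(k))), rep(1, 6))
  k2 <- k
  k2[, 3] <- k2[, 3] * 2
  sf <- size_factors(mk_counts(k2))
  expect_equal(unname(sf), c(1, 1, 2, 1, 1, 1))
  # Random matrix: factor ratios match a hand-rolled median-of-ratios.
  set.seed(8)
  kr <- matrix(rnbinom(100 * 6, mu = 80, size = 10) + 1, 100, 6)
  sf <- size_factors(mk_counts(kr))
  geo <- exp(rowMeans(log(kr)))
  raw <- apply(kr / geo, 2, median)
  expect_equal(unname(sf / sf[1]), unname(raw / raw[1]), tolerance = 1e-12)
})

test_that("size factors agree with DESeq2 up to a common scale", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  k <- matrix(rnbinom(200 * 6, mu = 100, size = 15) + 1, 200, 6)
  k[, 5] <- k[, 5] * 3
  sf <- size_factors(mk_counts(k))
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  # DESeq2 takes the median on the log scale; with an even feature count the
  # two middle values are averaged on different scales, so agreement is to
  # ~1e-4, not machine precision.
  expect_equal(unname(sf / sf[1]), unname(ref / ref[1]), tolerance = 1e-4)
})

test_that("dispersion estimation recovers the simulation regimes", {
  # Poisson data: dispersion estimates collapse toward zero.
  set.seed(0)
  kp <- matrix(rpois(3000 * 6, rep(exp(runif(3000, log(50), log(500))), 6)),
               3000, 6)
  ap <- estimate_dispersion(mk_counts(kp))
  expect_lt(median(ap), 0.02)
  # NB alpha = 0.2 with 20 replicates: median within [0.1, 0.3].
  kn <- matrix(rnbinom(500 * 40, mu = 100, size = 5), 500, 40)
  an <- estimate_dispersion(mk_counts(kn, conditions = rep(c("A", "B"),
                                                           each = 20)))
  expect_gte(median(an), 0.1)
  expect_lte(median(an), 0.3)
  # A constant feature drops to the floor (unit size factors isolate the
  # estimator from normalization).
  kc <- rbind(matrix(100, 1, 6), kn[1:50, 1:6])
  ac <- estimate_dispersion(mk_counts(kc), sf = rep(1, 6), alpha_min = 1e-8)
  expect_equal(unname(ac[1]), 1e-8)
})

test_that("nb_wald handles forced contrasts and degenerate features", {
  k <- matrix(100, 5, 6)
  res <- nb_wald(mk_counts(k), c("A", "B"))
  expect_true(all(res$log2FC == 0))
  expect_true(all(res$pvalue == 1))
  expect_true(all(res$direction == "none"))
  # Group means 100 vs 200 -> log2FC ~ 1 (up to the 0.5 pseudo-count).
  k2 <- cbind(matrix(100, 4, 3), matrix(200, 4, 3))
  res2 <- nb_wald(mk_counts(k2), c("A", "B"), sf = rep(1, 6))
  expect_equal(res2$log2FC, rep(log2(200.5 / 100.5), 4), tolerance = 1e-12)
  expect_true(all(res2$direction == "up"))
  # All-zero features are flagged with p = 1.
  k3 <- rbind(matrix(0, 2, 6), k2)
  res3 <- nb_wald(mk_counts(k3), c("A", "B"), sf = rep(1, 6))
  expect_true(all(res3$flag_zero[1:2]))
  expect_true(all(res3$pvalue[1:2] == 1))
  expect_true(all(res3$log2FC[1:2] == 0))
  # padj >= p and direction consistency.
  expect_true(all(res3$padj >= res3$pvalue))
  expect_error(nb_wald(mk_counts(k), c("A", "Z")), "contrast error")
})

test_that("doubling one condition shifts the Wald-scale log2FC by exactly 1", {
  set.seed(4)
  k <- matrix(rnbinom(200 * 6, mu = 150, size = 20) + 1, 200, 6)
  cm <- mk_counts(k)
  disp <- estimate_dispersion(cm, sf = rep(1, 6))
  res1 <- nb_wald(cm, c("A", "B"), sf = rep(1, 6), dispersions = disp)
  k2 <- k
  k2[, 4:6] <- k2[, 4:6] * 2
  res2 <- nb_wald(mk_counts(k2), c("A", "B"), sf = rep(1, 6),
                  dispersions = disp)
  # The statistic's fold change (stat * lfcSE, free of the pseudo-count)
  # moves by exactly +1 log2 unit.
  expect_equal(res2$stat * res2$lfcSE - res1$stat * res1$lfcSE,
               rep(1, 200), tolerance = 1e-9)
  # The reported (pseudo-counted) log2FC moves by +1 up to O(1/mean).
  expect_equal(res2$log2FC - res1$log2FC, rep(1, 200), tolerance = 0.02)
})

test_that("log fold changes track DESeq2 on a planted-effect matrix", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_count_matrix(300, 3, dispersion = 0.05, n_de = 50,
                               log2fc = 1.5, seed = 5)
  res <- nb_wald(sim$counts, c("A", "B"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts$counts, S4Vectors::DataFrame(condition = factor(
        sim$counts$samples$condition)), ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("condition", "B", "A"))
  })
  ok <- is.finite(ref$log2FoldChange)
  expect_gt(cor(res$log2FC[ok], ref$log2FoldChange[ok]), 0.98)
  # Planted features are called in the same direction.
  expect_gt(mean(res$direction[1:50] == "up"), 0.8)
})
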