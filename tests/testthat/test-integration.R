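# Enhancer-promoter pairing, hypergeometric overlap, preranked GSEA,
# methylation retention.

mk_de <- function(ids, dirs) {
  data.frame(feature = ids, direction = dirs, stringsAsFactors = FALSE)
}

test_that("pairing respects the window and matches the all-pairs oracle", {
  tss <- data.frame(gene = "g1", chrom = "chr1", tss = 700001)
  de_g <- mk_de("g1", "up")
  de_e <- mk_de("e1", "up")
  loc <- data.frame(id = "e1", chrom = "chr1", start = 99500, end = 100500)
  # Midpoint 100000, distance 600000 > 500000 -> no pair.
  expect_identical(nrow(pair_enhancer_promoter(de_e, loc, de_g, tss)), 0L)
  tss2 <- data.frame(gene = "g1", chrom = "chr1", tss = 600001)
  expect_identical(nrow(pair_enhancer_promoter(de_e, loc, de_g, tss2)), 1L)

  # Random 5x5 instances against the brute-force oracle.
  set.seed(9)
  for (i in 1:20) {
    enh <- data.frame(id = paste0("e", 1:5), chrom = sample(c("c1", "c2"), 5, TRUE),
                      start = sample(1e6, 5), stringsAsFactors = FALSE)
    enh$end <- enh$start + 1000
    enh$direction <- sample(c("up", "down"), 5, TRUE)
    genes <- data.frame(gene = paste0("g", 1:5),
                        chrom = sample(c("c1", "c2"), 5, TRUE),
                        tss = sample(1e6, 5),
                        direction = sample(c("up", "down", "none"), 5, TRUE),
                        stringsAsFactors = FALSE)
    for (rc in c(TRUE, FALSE)) {
      got <- pair_enhancer_promoter(
        mk_de(enh$id, enh$direction), enh,
        mk_de(genes$gene, genes$direction), genes,
        window = 3e5, require_concordant = rc)
      exp <- oracle_ep_pairs(enh, genes[genes$direction != "none", ], 3e5, rc)
      key <- function(d) sort(paste(d$enhancer, d$gene, d$distance))
      expect_identical(key(got), key(exp), info = paste(i, rc))
    }
  }
})

test_that("discordant distractors are excluded only when required", {
  enh <- data.frame(id = c("eU", "eD"), chrom = "c1",
                    start = c(1000, 3000), end = c(2000, 4000),
                    direction = c("up", "down"))
  genes <- data.frame(gene = "gU", chrom = "c1", tss = 5000,
                      direction = "up")
  conc <- pair_enhancer_promoter(mk_de(enh$id, enh$direction), enh,
                                 mk_de(genes$gene, genes$direction), genes,
                                 window = 1e5, require_concordant = TRUE)
  expect_identical(conc$enhancer, "eU")
  all_p <- pair_enhancer_promoter(mk_de(enh$id, enh$direction), enh,
                                  mk_de(genes$gene, genes$direction), genes,
                                  window = 1e5, require_concordant = FALSE)
  expect_identical(sort(all_p$enhancer), c("eD", "eU"))
  expect_identical(all_p$concordant[all_p$enhancer == "eD"], FALSE)
})

test_that("overlap_test reproduces the enumeration example", {
  universe <- sprintf("u%02d", 1:20)
  a <- universe[1:5]
  b <- c(universe[1:3], universe[10])  # overlap 3
  ot <- overlap_test(a, b, universe)
  # (C(5,3) C(15,1) + C(5,4) C(15,0)) / C(20,4)
  manual <- (choose(5, 3) * choose(15, 1) + choose(5, 4) * choose(15, 0)) /
    choose(20, 4)
  expect_equal(ot$p, manual, tolerance = 1e-12)
  expect_equal(round(ot$p, 4), 0.032)
  expect_identical(ot$overlap, 3L)
  # k = 0 gives P(X >= 0) = 1.
  expect_equal(overlap_test(universe[1:4], universe[11:14], universe)$p, 1)
  # Degenerate A = B = universe.
  deg <- overlap_test(universe, universe, universe)
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
  expect_error(overlap_test("zz", universe[1], universe), "subsets")
  expect_error(overlap_test("a", "b", character(0)), "empty universe")
})

test_that("overlap_test equals enumeration over random instances", {
  set.seed(12)
  for (i in 1:200) {
    N <- sample(5:60, 1)
    universe <- sprintf("v%02d", 1:N)
    a <- sample(universe, sample(1:N, 1))
    b <- sample(universe, sample(1:N, 1))
    ot <- overlap_test(a, b, universe)
    expect_equal(ot$p,
                 oracle_hyper_upper(length(intersect(a, b)), length(a), N,
                                    length(b)),
                 tolerance = 1e-10, info = i)
  }
})

test_that("GSEA matches a hand-computed running sum and extremal behaviour", {
  scores <- stats::setNames(10:1, paste0("g", 1:10))
  gs <- preranked_gsea(scores, c("g1", "g3"), n_perm = 200, seed = 0)
  expect_equal(gs$es, oracle_gsea_es(scores, c("g1", "g3")), tolerance = 1e-12)
  # Hand value: hit weights |10|/18 and |8|/18, miss decrement 1/8;
  # the running sum peaks at rank 3.
  expect_equal(gs$es, 10 / 18 - 1 / 8 + 8 / 18, tolerance = 1e-12)
  # A set formed by the top genes is maximal among sampled same-size sets.
  top <- preranked_gsea(scores, c("g1", "g2", "g3"), n_perm = 100, seed = 1)
  expect_gt(top$es, 0)
  rand_es <- with_seed(2, replicate(50, {
    oracle_gsea_es(scores, sample(names(scores), 3))
  }))
  expect_gte(top$es, max(rand_es) - 1e-12)
  # NES sign equals ES sign; |ES| <= 1.
  expect_identical(sign(top$nes), sign(top$es))
  expect_lte(abs(top$es), 1)
  expect_error(preranked_gsea(scores, "zzz"), "disjoint")
})

test_that("classical KS symmetry holds under ranking reversal", {
  scores <- stats::setNames(c(5, 4, 2, 1, -1, -3, -4, -6, -7, -9),
                            paste0("g", 1:10))
  set <- c("g2", "g3", "g9")
  es_fwd <- methenh:::gsea_es(scores[order(-scores)],
                              names(sort(-scores)) %in% set, weight = 0)
  rev_scores <- -scores
  es_rev <- methenh:::gsea_es(rev_scores[order(-rev_scores)],
                              names(sort(-rev_scores)) %in% set, weight = 0)
  expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
  # With weight 1 only the sign flip is guaranteed.
  a <- preranked_gsea(scores, set, n_perm = 50, seed = 3)
  b <- preranked_gsea(-scores, set, n_perm = 50, seed = 3)
  expect_identical(sign(b$es), -sign(a$es))
})

test_that("a planted up-regulated set yields small permutation p", {
  set.seed(6)
  scores <- stats::setNames(rnorm(500), sprintf("g%03d", 1:500))
  planted <- names(sort(scores, decreasing = TRUE))[1:25]
  gs <- preranked_gsea(scores, planted, n_perm = 1000, seed = 0)
  expect_lte(gs$p, 0.01)
  expect_gt(gs$nes, 1)
})

test_that("methylation retention counts retained probes per the threshold", {
  design <- data.frame(sample = c("b1", "b2"), condition = "base",
                       replicate = 1:2)
  design2 <- data.frame(sample = c("t1", "t2"), condition = "treat",
                        replicate = 1:2)
  v <- matrix(0.6, 10, 2, dimnames = list(sprintf("p%02d", 1:10),
                                          c("b1", "b2")))
  base <- beta_matrix(v, design, "BS")
  w <- v
  colnames(w) <- c("t1", "t2")
  treat <- beta_matrix(w, design2, "BS")
  r0 <- methylation_retention(base, treat, rownames(v))
  expect_equal(r0$retained_fraction, 1)
  expect_equal(r0$mean_delta, 0)
  # Half the probes shifted by -0.2 -> retained fraction 0.5.
  w2 <- w
  w2[1:5, ] <- w2[1:5, ] - 0.2
  r1 <- methylation_retention(base, beta_matrix(w2, design2, "BS"),
                              rownames(v))
  expect_equal(r1$retained_fraction, 0.5)
  expect_equal(r1$mean_delta, -0.1)
  expect_error(methylation_retention(base, treat, c("p01", "nope")),
               "missing.*nope")
})

test_that("GSEA agrees with fgsea's enrichment score", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  scores <- stats::setNames(rnorm(200), sprintf("f%03d", 1:200))
  set <- sample(names(scores), 15)
  es <- preranked_gsea(scores, set, n_perm = 10, seed = 1)$es
  ord <- order(-scores, names(scores))
  ref <- fgsea::calcGseaStat(unname(scores[ord]),
                             which(names(scores)[ord] %in% set),
                             gseaParam = 1)
  expect_equal(es, ref, tolerance = 1e-10)
})
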