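# Probe-context annotation (feature priority, CpG distance classes) and
# exact Fisher enrichment.

test_that("CpG classes follow the island-distance bands with inclusive bounds", {
  ann <- toy_annotation()
  # Island cgi1 = [50001, 51000]; probes inside, at 2000, 3000, 4000, 4001 bp.
  ctx <- annotate_probes(toy_probes(c(50500, 53000, 54000, 55000, 55001)), ann)
  expect_identical(ctx$cpg_class,
                   c("island", "shore", "shelf", "shelf", "open_sea"))
  expect_identical(ctx$dist_to_island, c(0, 2000, 3000, 4000, 4001))
})

test_that("island distances match a brute-force oracle on random probes", {
  ann <- small_annotation()
  probes <- ann$probes[with_seed(5, sample(length(ann$probes), 200))]
  ctx <- annotate_probes(probes, ann)
  isl <- data.frame(
    start = GenomicRanges::start(ann$cpg_islands),
    end = GenomicRanges::end(ann$cpg_islands))
  pos <- GenomicRanges::start(probes)
  d_oracle <- vapply(pos, function(p) {
    inside <- any(p >= isl$start & p <= isl$end)
    if (inside) 0 else min(pmin(abs(p - isl$start), abs(p - isl$end)))
  }, numeric(1))
  expect_equal(ctx$dist_to_island, d_oracle)
})

test_that("feature classes resolve overlaps by the documented priority", {
  ann <- toy_annotation()
  # 10200 is inside gene gA AND its promoter (promoter wins); 20100 is in
  # the enhancer; 12000 in the gene body; 70000 intergenic.
  ctx <- annotate_probes(toy_probes(c(10200, 20100, 12000, 70000)), ann)
  expect_identical(ctx$feature_class,
                   c("promoter", "enhancer", "gene_body", "intergenic"))
  bad <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(5, 5), probe = "x")
  expect_error(annotate_probes(bad, ann), "unknown chromosome")
})

test_that("fisher_enrichment matches enumeration on the worked example", {
  universe <- sprintf("u%03d", 1:100)
  classes <- stats::setNames(rep(c("enhancer", "other"), c(20, 80)), universe)
  selected <- c(universe[1:6], universe[21:24]) # 6 of 10 in enhancers
  res <- fisher_enrichment(selected, universe, classes)
  enh <- res[res$class == "enhancer", ]
  expect_equal(enh$p_greater, oracle_hyper_upper(6, 20, 100, 10),
               tolerance = 1e-12)
  expect_equal(enh$p_less, oracle_hyper_lower(6, 20, 100, 10),
               tolerance = 1e-12)
  expect_identical(c(enh$selected_in, enh$selected_out,
                     enh$unselected_in, enh$unselected_out),
                   c(6L, 4L, 14L, 76L))
  # Counts always sum to the universe.
  expect_true(all(rowSums(res[, 2:5]) == 100))
  # Cross-check against stats::fisher.test one-sided p.
  ft <- stats::fisher.test(matrix(c(6, 4, 14, 76), 2, byrow = TRUE),
                           alternative = "greater")
  expect_equal(enh$p_greater, ft$p.value, tolerance = 1e-10)
})

test_that("enrichment p-values equal enumeration over random 2x2 tables", {
  set.seed(42)
  for (i in 1:100) {
    N <- sample(10:50, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    universe <- sprintf("x%02d", 1:N)
    classes <- stats::setNames(
      rep(c("in", "out"), c(K, N - K)), universe)
    selected <- sample(universe, n)
    res <- fisher_enrichment(selected, universe, classes)
    a <- res$selected_in[res$class == "in"]
    expect_equal(res$p_greater[res$class == "in"],
                 oracle_hyper_upper(a, K, N, n), tolerance = 1e-10)
    expect_equal(res$p_less[res$class == "in"],
                 oracle_hyper_lower(a, K, N, n), tolerance = 1e-10)
    # The two one-sided tails overlap at the observed table.
    expect_gte(res$p_greater[1] + res$p_less[1], 1 - 1e-12)
  }
})

test_that("uniformly drawn selections give calibrated enrichment p-values", {
  universe <- sprintf("u%03d", 1:200)
  classes <- stats::setNames(rep(c("a", "b"), c(60, 140)), universe)
  hits <- with_seed(0, vapply(1:500, function(i) {
    res <- fisher_enrichment(sample(universe, 30), universe, classes)
    res$p_greater[res$class == "a"] < 0.05
  }, logical(1)))
  # One-sided exact tests are conservative; the rejection rate must not
  # exceed the nominal level (binomial upper bound) by chance.
  expect_lt(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("empty selections are flagged with p = 1 everywhere", {
  universe <- letters[1:10]
  classes <- stats::setNames(rep(c("x", "y"), 5), universe)
  res <- fisher_enrichment(character(0), universe, classes)
  expect_true(all(res$p_greater == 1) && all(res$p_less == 1))
  expect_true(isTRUE(attr(res, "empty_selection")))
  expect_error(fisher_enrichment("zzz", universe, classes), "not in universe")
})
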