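# Coverage segmentation, unit classification (bidirectional merging),
# quantification.

test_that("segmentation handles the forced examples", {
  p <- segment_params(tau = 5, gap = 20, min_len = 30)
  expect_identical(nrow(segment_coverage(rep(0, 50), p, 10)), 0L)
  # [0,7,8,0,0,9,0]: the 20 bp gap merges; length 50 >= 30.
  got <- segment_coverage(c(0, 7, 8, 0, 0, 9, 0), p, 10)
  expect_equal(got$start, 10)
  expect_equal(got$end, 60)
  # Uniform coverage spans the whole track.
  u <- segment_coverage(rep(6, 100), p, 10)
  expect_equal(c(u$start, u$end), c(0, 1000))
  # A run shorter than min_len is discarded.
  expect_identical(nrow(segment_coverage(c(0, 9, 9, 0), p, 10)), 0L)
})

test_that("segmentation equals the brute-force scan on random tracks", {
  set.seed(3)
  for (i in 1:30) {
    n <- sample(50:2000, 1)
    x <- rpois(n, 0.8) + sample(0:4, n, replace = TRUE) *
      rbinom(n, 1, 0.1)
    tau <- sample(2:5, 1)
    gap <- sample(c(0, 10, 30, 50), 1)
    L <- sample(c(10, 30, 80), 1)
    got <- segment_coverage(x, segment_params(tau = tau, gap = gap,
                                              min_len = L), 10)
    exp <- oracle_segment(x, tau, gap, L, 10)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(exp)), info = i)
    # Structural guarantees: respects min_len, sorted, non-overlapping.
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
    if (nrow(got) > 0) expect_true(all(got$end - got$start >= L))
  }
})

test_that("classification separates genic from eRNA and merges bidirectional pairs", {
  ann <- toy_annotation() # genes [10001,15000]+ and [40001,44000]-
  segs <- list(
    "+" = data.frame(chrom = "chrT",
                     start = c(11000, 5000, 60000),
                     end = c(12000, 5400, 60500)),
    "-" = data.frame(chrom = "chrT",
                     start = c(4700, 90000),
                     end = c(5100, 90100))
  )
  units <- classify_units(segs, ann, segment_params(tau = 5, d_pair = 1000))
  # Overlapping a gene body -> genic, never eRNA.
  g <- units[units$start == 11000, ]
  expect_identical(g$class, "genic")
  # + [5000,5400) and - [4700,5100) overlap -> merged union [4700,5400).
  m <- units[units$class == "eRNA" & units$strand == "*", ]
  expect_identical(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(4700, 5400))
  expect_identical(m$src_plus, "chrT:5000-5400")
  expect_identical(m$src_minus, "chrT:4700-5100")
  expect_identical(m$id, "eRNA.chrT:4700-5400")
  # Unpaired long interval -> eRNA; short -> other.
  expect_identical(units$class[units$start == 60000], "eRNA")
  expect_identical(units$class[units$start == 90000], "other")
})

test_that("genic exclusion respects the d_ex margin", {
  ann <- toy_annotation()
  seg_near <- list("+" = data.frame(chrom = "chrT", start = 15500, end = 15900),
                   "-" = data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0)))
  # Gene ends at 15000; margin 1000 covers up to 16000 -> genic.
  u1 <- classify_units(seg_near, ann, segment_params(tau = 5, d_ex = 1000))
  expect_identical(u1$class, "genic")
  u2 <- classify_units(seg_near, ann, segment_params(tau = 5, d_ex = 100))
  expect_identical(u2$class, "eRNA")
})

test_that("the eRNA set does not depend on input row order", {
  ann <- small_annotation()
  txn <- small_transcription()
  units <- annotate_ernas(txn$coverage, ann)
  pooled <- pool_coverage(txn$coverage)
  p <- segment_params(tau = attr(units, "tau"))
  segs <- lapply(c("+", "-"), function(st) {
    df <- segment_coverage(pooled[[st]][["chr1"]], p, 10)
    cbind(chrom = "chr1", df)
  })
  names(segs) <- c("+", "-")
  shuffled <- lapply(segs, function(df) df[rev(seq_len(nrow(df))), ])
  a <- classify_units(segs, ann, p)
  b <- classify_units(shuffled, ann, p)
  expect_identical(a$id[a$class == "eRNA"], b$id[b$class == "eRNA"])
})

test_that("quantification sums bins with strand awareness and linearity", {
  cl <- c(chrT = 1000)
  design <- data.frame(sample = c("s1", "s2"), condition = "A",
                       replicate = 1:2)
  zero <- lapply(stats::setNames(nm = c("s1", "s2")), function(s) {
    list("+" = list(chrT = rep(0, 100)), "-" = list(chrT = rep(0, 100)))
  })
  cs0 <- coverage_set(zero, 10, cl, design)
  units <- data.frame(id = c("e1", "t1"), chrom = "chrT",
                      start = c(100, 300), end = c(200, 400),
                      strand = c("*", "+"), class = c("eRNA", "genic"))
  expect_true(all(quantify_units(units, cs0)$counts == 0))
  # Rectangular block: height 4 over the 10 bins of e1 on + strand.
  vals <- zero
  vals$s1[["+"]]$chrT[11:20] <- 4
  vals$s1[["-"]]$chrT[11:20] <- 1
  cs1 <- coverage_set(vals, 10, cl, design)
  k <- quantify_units(units, cs1)$counts
  expect_identical(k["e1", "s1"], 50L) # both strands for eRNA: 40 + 10
  expect_identical(k["e1", "s2"], 0L)
  # Doubling a sample's track doubles its counts.
  vals2 <- vals
  vals2$s1 <- lapply(vals$s1, function(st) lapply(st, function(v) v * 2))
  k2 <- quantify_units(units, coverage_set(vals2, 10, cl, design))$counts
  expect_identical(k2[, "s1"], k[, "s1"] * 2L)
  # Unknown chromosome errors.
  bad <- units
  bad$chrom <- "chrZ"
  expect_error(quantify_units(bad, cs1), "quantification error")
})

test_that("coverage round-trips through bedGraph", {
  txn <- small_transcription()
  dir <- withr::local_tempdir()
  write_coverage(txn$coverage, dir)
  back <- read_coverage(dir, small_annotation()$chrom_lengths)
  s <- txn$coverage$samples$sample[1]
  expect_equal(back$values[[s]][["+"]][["chr1"]],
               txn$coverage$values[[s]][["+"]][["chr1"]])
  expect_equal(back$values[[s]][["-"]][["chr1"]],
               txn$coverage$values[[s]][["-"]][["chr1"]])
})

test_that("the q90 threshold option resolves from pooled nonzero bins", {
  txn <- small_transcription()
  pooled <- pool_coverage(txn$coverage)
  vals <- unlist(lapply(pooled, function(st) lapply(st, function(x) x[x > 0])),
                 use.names = FALSE)
  expect_equal(methenh:::resolve_tau(segment_params(tau = "q90"), pooled),
               max(1, unname(quantile(vals, 0.9))))
  expect_equal(methenh:::resolve_tau(segment_params(tau = 7.5), pooled), 7.5)
  expect_equal(methenh:::resolve_tau(segment_params(), pooled),
               ceiling(0.75 * 8))
})
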