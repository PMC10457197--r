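# PWM scanning (log-odds, strands, N handling) and sequence-level motif
# enrichment.

test_that("a degenerate PWM hits exactly at substring matches on both strands", {
  cons <- "TGACTCA"
  mat <- t(vapply(strsplit(cons, "")[[1]], function(b) {
    v <- c(A = 0, C = 0, G = 0, T = 0)
    v[b] <- 1
    v
  }, numeric(4)))
  pw <- pwm(mat, id = "ap1")
  seqs <- c(
    one = paste0("AAAA", cons, "AAAA"),            # forward at 5
    two = paste0("CC", "TGAGTCA", "CC"),           # revcomp(TGACTCA) = TGAGTCA
    none = "ACGTACGTACGTACGT"
  )
  sc <- scan_sequences(seqs, pw, score_fraction = 1)
  expect_true(sc$presence[["one"]])
  expect_true(sc$presence[["two"]])
  expect_false(sc$presence[["none"]])
  fwd <- sc$hits[sc$hits$seq == "one", ]
  expect_equal(fwd$pos, 5)
  expect_identical(fwd$strand, "+")
  rev <- sc$hits[sc$hits$seq == "two", ]
  expect_identical(rev$strand, "-")
  # Oracle: regexpr on the sequence and its reverse complement.
  expect_equal(as.integer(regexpr(cons, seqs[["one"]])), fwd$pos)
})

test_that("window scores equal the hand-computed log-odds sum", {
  mat <- rbind(c(0.7, 0.1, 0.1, 0.1),
               c(0.1, 0.7, 0.1, 0.1),
               c(0.1, 0.1, 0.7, 0.1),
               c(0.1, 0.1, 0.1, 0.7))
  pw <- pwm(mat, id = "m", pseudocount = 1e-3)
  # Score of "ACGT": sum of log2(p'(b_i) / 0.25) with the pseudocount mix.
  pp <- (mat + 1e-3) / (1 + 4e-3)
  hand <- sum(log2(diag(pp) / 0.25))
  sc <- scan_sequences(c(x = "ACGT"), pw, score_fraction = 1e-9)
  fwd <- sc$hits[sc$hits$strand == "+", ]
  expect_equal(fwd$score, hand, tolerance = 1e-12)
  expect_equal(pw$max_score, hand, tolerance = 1e-12)
  # N positions contribute zero (background).
  scn <- scan_sequences(c(x = "ANGT"), pw, score_fraction = 1e-9)
  fn <- scn$hits[scn$hits$strand == "+", ]
  expect_equal(fn$score, hand - log2(pp[2, 2] / 0.25), tolerance = 1e-12)
})

test_that("presence is invariant under reverse complement of the inputs", {
  pw <- random_pwms(1, length = 6, seed = 2)[[1]]
  seqs <- random_sequences(40, 120, seed = 3)
  seqs[1:10] <- plant_motif(seqs[1:10], pw, fraction = 1, seed = 4)
  rc <- vapply(seqs, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  a <- scan_sequences(seqs, pw, 0.8)$presence
  b <- scan_sequences(rc, pw, 0.8)$presence
  expect_identical(unname(a), unname(b))
})

test_that("sequences shorter than the motif are flagged, not scored", {
  pw <- random_pwms(1, length = 8, seed = 5)[[1]]
  sc <- scan_sequences(c(tiny = "ACGT", ok = "ACGTACGTACGT"), pw, 0.8)
  expect_identical(sc$short, "tiny")
  expect_false(sc$presence[["tiny"]])
})

test_that("target = background gives no significant motif after BH", {
  seqs <- random_sequences(60, 150, seed = 6)
  pwms <- random_pwms(6, length = 8, seed = 7)
  enr <- motif_enrichment(seqs, seqs, pwms, score_fraction = 0.8)
  expect_true(all(enr$p_adj > 0.05))
  expect_equal(enr$pct_targets, enr$pct_background)
})

test_that("a planted motif is recovered against decoys", {
  pw <- methenh:::planted_pwm()
  targets <- plant_motif(random_sequences(50, 200, seed = 8), pw,
                         fraction = 0.9, seed = 9)
  background <- random_sequences(150, 200, seed = 10)
  pwms <- c(list(planted = pw), random_pwms(3, length = 8, seed = 11))
  enr <- motif_enrichment(targets, background, pwms, score_fraction = 0.8)
  expect_identical(enr$motif[1], "planted")
  expect_gte(enr$pct_targets[1], 80)
  expect_lt(enr$p_adj[1], 1e-6)
})

test_that("the presence Fisher test shares the exact hypergeometric core", {
  pw <- methenh:::planted_pwm()
  targets <- plant_motif(random_sequences(30, 100, seed = 12), pw, 0.8,
                         seed = 13)
  background <- random_sequences(60, 100, seed = 14)
  enr <- motif_enrichment(targets, background, list(pw), 0.8)
  a <- round(enr$pct_targets * enr$n_targets / 100)
  b <- round(enr$pct_background * enr$n_background / 100)
  expect_equal(enr$p,
               oracle_hyper_upper(a, a + b, enr$n_targets + enr$n_background,
                                  enr$n_targets),
               tolerance = 1e-10)
})

test_that("empty motif lists give an empty table", {
  expect_identical(nrow(motif_enrichment(random_sequences(5, 50, seed = 1),
                                         NULL, list())), 0L)
})

test_that("PWMs and FASTA round-trip through their text formats", {
  pwms <- random_pwms(3, length = 6, seed = 15)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pwms(pwms, path)
  back <- read_pwms(path)
  expect_identical(names(back), names(pwms))
  expect_equal(back[[2]]$mat, pwms[[2]]$mat, tolerance = 1e-7,
               ignore_attr = TRUE)
  seqs <- random_sequences(4, 80, seed = 16)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
  expect_error(pwm(matrix(0.3, 4, 4)), "sum to 1")
  expect_error(pwm(matrix(0.25, 3, 4)), "length")
})
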