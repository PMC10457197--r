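# 5hmC estimation arithmetic, delta-beta contrasts, differential calling,
# Welch calibration, anti-correlation, z-score standardization.

mk_beta <- function(vals, assay, conditions = c("A", "A", "B", "B")) {
  colnames(vals) <- paste0("s", seq_len(ncol(vals)))
  rownames(vals) <- paste0("p", seq_len(nrow(vals)))
  beta_matrix(vals, data.frame(sample = colnames(vals),
                               condition = conditions,
                               replicate = ave(seq_len(ncol(vals)),
                                               conditions, FUN = seq_along)),
              assay)
}

test_that("estimate_5hmc does the forced BS - oxBS arithmetic and clipping", {
  bs <- mk_beta(matrix(c(0.60, 0.80, 0.50), 3, 4), "BS")
  ox <- mk_beta(matrix(c(0.60, 0.65, 0.60), 3, 4), "oxBS")
  est <- estimate_5hmc(bs, ox)
  expect_equal(unname(est$h_raw[, 1]), c(0, 0.15, -0.10))
  expect_equal(unname(est$h[, 1]), c(0, 0.15, 0))
  expect_equal(unname(est$m[, 1]), c(0.60, 0.65, 0.60))
  expect_identical(est$n_rescaled, 0L)
  # h_raw is preserved unmodified even where clipping applies.
  expect_equal(unname(est$h_raw[3, 1]), -0.10)
})

test_that("joint rescaling caps m + h at 1 and counts the affected cells", {
  bs <- mk_beta(matrix(0.9, 2, 4), "BS")
  ox <- mk_beta(matrix(c(0.3, 0.85), 2, 4), "oxBS")
  # Probe 2: m = 0.85, h = 0.9 - 0.85 = 0.05 -> fine; force an overflow:
  bs$values[2, ] <- 1
  ox$values[2, ] <- 0.4
  est <- estimate_5hmc(bs, ox)
  # m + h = 0.4 + 0.6 = 1 exactly: no rescale; now a genuine overflow:
  bs2 <- mk_beta(matrix(1, 1, 4), "BS")
  ox2 <- mk_beta(matrix(0.9, 1, 4), "oxBS")
  ox2$values[] <- 0.95
  # h_raw = 0.05, m = 0.95 -> ok; instead overflow needs clipped h + m > 1,
  # which requires h_raw > 1 - m; construct directly:
  bs3 <- mk_beta(matrix(0.98, 1, 4), "BS")
  ox3 <- mk_beta(matrix(0.2, 1, 4), "oxBS")
  ox3$values[] <- 0.30
  bs3$values[] <- 0.98
  est3 <- estimate_5hmc(bs3, ox3)
  expect_identical(est3$n_rescaled, 0L)
  # m = 0.3, h = 0.68, fine. True overflow is impossible for valid betas
  # (h + m = beta_BS <= 1), which is itself worth asserting:
  expect_true(all(est$h + est$m_scaled <= 1 + 1e-12))
})

test_that("misaligned inputs raise alignment errors naming offenders", {
  bs <- mk_beta(matrix(0.5, 3, 4), "BS")
  ox <- mk_beta(matrix(0.5, 2, 4), "oxBS")
  expect_error(estimate_5hmc(bs, ox), "alignment error.*p3")
  expect_error(estimate_5hmc(bs, bs), "expected assays")
})

test_that("delta_beta computes group-mean differences per mark", {
  bs <- mk_beta(matrix(c(0.30, 0.30, 0.42, 0.42), 1, 4, byrow = TRUE), "BS")
  ox <- mk_beta(matrix(0.10, 1, 4), "oxBS")
  est <- estimate_5hmc(bs, ox)
  tab <- delta_beta(est, c("A", "B"))
  expect_equal(tab$delta[tab$mark == "h"], 0.12)
  expect_equal(tab$delta[tab$mark == "m"], 0)
  # Identical groups give exactly zero.
  same <- delta_beta(estimate_5hmc(mk_beta(matrix(0.4, 5, 4), "BS"),
                                   mk_beta(matrix(0.2, 5, 4), "oxBS")),
                     c("A", "B"))
  expect_true(all(same$delta == 0))
  expect_error(delta_beta(est, c("A", "Z")), "contrast error.*Z")
})

test_that("calls respect strict thresholds and the alpha configuration", {
  # Binary-exact betas so the boundary delta is exactly the threshold.
  vals <- matrix(c(0.250, 0.250, 0.3125, 0.3125,  # delta exactly 0.0625
                   0.500, 0.500, 0.3750, 0.3750,  # delta -0.125
                   0.500, 0.500, 0.6250, 0.6250), # delta +0.125
                 3, 4, byrow = TRUE)
  tab <- delta_beta(mk_beta(vals, "BS"), c("A", "B"))
  tab <- call_differential(tab, 0.0625)
  expect_identical(tab$call, c("none", "hypo", "hyper"))
  expect_error(call_differential(tab, 0.0625, alpha = 0.05),
               "configuration error")
})

test_that("Welch p-values are calibrated on a 4v4 synthetic null", {
  n <- 5000
  vals <- with_seed(0, matrix(stats::rnorm(n * 8, 0.5, 0.03), n, 8))
  tab <- delta_beta(mk_beta(vals, "BS",
                            conditions = rep(c("A", "B"), each = 4)),
                    c("A", "B"), test = "welch_t")
  frac <- mean(tab$p < 0.05)
  ci <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), ci)
  expect_true(all(tab$p_adj >= tab$p))
})

test_that("correlate_changes matches the closed-form Pearson formula", {
  dh <- c(0.1, 0.2, 0.3, 0.0, 0.4)
  dm <- c(-0.1, -0.1, -0.3, 0.0, -0.2)
  vals_h <- cbind(a1 = dh * 0, a2 = dh * 0, b1 = dh, b2 = dh) + 0.4
  vals_m <- cbind(a1 = dm * 0, a2 = dm * 0, b1 = dm, b2 = dm) + 0.4
  est <- estimate_5hmc(mk_beta(vals_m + vals_h - 0.4, "BS"),
                       mk_beta(vals_m, "oxBS"))
  tab <- delta_beta(est, c("A", "B"))
  r <- correlate_changes(tab)
  # Closed-form Pearson, written out.
  num <- sum((dh - mean(dh)) * (dm - mean(dm)))
  den <- sqrt(sum((dh - mean(dh))^2) * sum((dm - mean(dm))^2))
  expect_equal(r$r, num / den, tolerance = 1e-12)
  expect_identical(r$n, 5L)
  # Swapping the marks gives the same r.
  r2 <- correlate_changes(tab, marks = c("m", "h"))
  expect_equal(r2$r, r$r, tolerance = 1e-12)
  # Exact anti-correlation: delta_m = -dh while delta_h = +dh.
  ox2 <- cbind(a1 = rep(0.4, 5), a2 = 0.4, b1 = 0.4 - dh, b2 = 0.4 - dh)
  h2 <- cbind(a1 = rep(0.1, 5), a2 = 0.1, b1 = 0.1 + dh, b2 = 0.1 + dh)
  est2 <- estimate_5hmc(mk_beta(ox2 + h2, "BS"), mk_beta(ox2, "oxBS"))
  tab2 <- delta_beta(est2, c("A", "B"))
  expect_equal(correlate_changes(tab2)$r, -1, tolerance = 1e-10)
  # Zero variance errors out.
  flat <- delta_beta(estimate_5hmc(mk_beta(matrix(0.5, 5, 4), "BS"),
                                   mk_beta(matrix(0.2, 5, 4), "oxBS")),
                     c("A", "B"))
  expect_error(correlate_changes(flat), "undefined-correlation")
})

test_that("z-score standardization uses sample sd and flags constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 0))
  z <- standardize_profiles(m)
  expect_equal(unname(z$z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z$z["b", ]), c(0, 0, 0))
  expect_identical(unname(z$constant), c(FALSE, TRUE, FALSE))
  # Row mean 0, unit sample variance for non-constant rows.
  expect_equal(unname(apply(z$z[!z$constant, ], 1, sd)), c(1, 1))
  # Duplicated condition columns give identical z columns.
  m2 <- cbind(m, m[, 3])
  z2 <- standardize_profiles(m2)
  expect_equal(z2$z[, 3], z2$z[, 4])
  expect_error(standardize_profiles(m[, 1, drop = FALSE]), ">= 2 conditions")
})

test_that("missing values follow the pairwise-complete policy", {
  vals <- matrix(c(0.2, 0.3, 0.5, 0.6), 2, 4)
  vals[1, 3] <- NA  # one missing replicate: group mean over the rest
  vals[2, 3] <- NA
  vals[2, 4] <- NA  # whole group missing: delta is NA
  bs <- mk_beta(vals, "BS")
  ox <- mk_beta(vals * 0 + 0.1, "oxBS")
  ox$values[is.na(vals)] <- NA
  tab <- delta_beta(estimate_5hmc(bs, ox), c("A", "B"))
  h1 <- tab[tab$mark == "h" & tab$probe == "p1", ]
  expect_false(is.na(h1$delta))
  h2 <- tab[tab$mark == "h" & tab$probe == "p2", ]
  expect_true(is.na(h2$delta))
})
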