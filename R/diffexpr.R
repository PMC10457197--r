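# Negative-binomial differential expression: median-of-ratios size factors,
# method-of-moments dispersion with trend shrinkage, Wald test, BH adjustment.

#' Benjamini-Hochberg step-up adjustment
#'
#' Plain step-up: order the m p-values increasingly, compute `p[i] * m / i`,
#' and enforce monotonicity from the largest rank down; ties share the same
#' adjusted value. `NA`s are left in place and excluded from m.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("bh_adjust: p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  o <- ok[order(p[ok], decreasing = TRUE)]
  # (m / rank) first: the rank-m factor is exactly 1, so the largest
  # adjusted p equals its raw p bit for bit.
  out[o] <- pmin(1, cummin(p[o] * (m / seq(m, 1))))
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the ratio
#' of its count to the feature's geometric mean across samples, computed over
#' features with nonzero counts in every sample; the factors are then
#' rescaled to unit median, so an exactly doubled sample gets factor 2 while
#' unchanged samples keep factor 1 (only factor ratios matter downstream).
#' If no feature is nonzero in all samples, a pseudo-reference fallback
#' (geometric mean over positive counts only) is applied with a warning.
#'
#' @param counts A [count_matrix()] or plain counts matrix.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else counts
  stopifnot(is.matrix(k))
  all_pos <- rowSums(k == 0) == 0
  if (any(all_pos)) {
    logk <- log(k[all_pos, , drop = FALSE])
    ref <- rowMeans(logk)
    sf <- apply(exp(logk - ref), 2, stats::median)
  } else {
    warnf("size_factors: no feature nonzero in all samples; using pseudo-reference over positive counts")
    lk <- log(k)
    lk[!is.finite(lk)] <- NA
    ref <- rowMeans(lk, na.rm = TRUE)
    use <- is.finite(ref) & rowSums(!is.na(lk)) >= 1
    if (!any(use)) stopf("size-factor error: all counts zero")
    sf <- apply(exp(lk[use, , drop = FALSE] - ref[use]), 2, stats::median, na.rm = TRUE)
  }
  if (any(!is.finite(sf) | sf <= 0)) stopf("size-factor error: nonpositive factor")
  sf <- sf / stats::median(sf)
  stats::setNames(sf, colnames(k))
}

#' Per-feature NB dispersion with trend shrinkage
#'
#' Method-of-moments within conditions on normalized counts:
#' `alpha_raw = max((var - mean) / mean^2, alpha_min)` with mean and variance
#' pooled across conditions having >= 2 replicates. A log-linear mean-
#' dispersion trend is fitted over features with above-floor raw estimates,
#' each estimate is shrunk halfway (in log space, weight `shrink`) toward the
#' trend, and the result is floored at the trend value: with very few
#' replicates a per-feature estimate below the trend is more likely
#' underestimation than signal, and flooring guards the Wald test's type-I
#' error. Features with zero pooled variance get `alpha_min`.
#'
#' @param counts A [count_matrix()] or plain counts matrix.
#' @param sf Size factors (default [size_factors()]).
#' @param conditions Condition label per sample (default from the
#'   `count_matrix` sample sheet).
#' @param alpha_min Dispersion floor.
#' @param shrink Log-space shrinkage weight toward the trend.
#' @return Named numeric vector of dispersions, with the fitted trend
#'   coefficients in attribute `trend`.
#' @export
estimate_dispersion <- function(counts, sf = NULL, conditions = NULL,
                                alpha_min = 1e-8, shrink = 0.5) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else counts
  conditions <- conditions %||%
    if (inherits(counts, "count_matrix")) counts$samples$condition else
      stopf("estimate_dispersion: 'conditions' required for a plain matrix")
  sf <- sf %||% size_factors(k)
  norm <- sweep(k, 2, sf, "/")
  conds <- unique(conditions)
  reps <- table(conditions)[conds]
  use_conds <- conds[reps >= 2]
  if (!length(use_conds)) stopf("estimate_dispersion: need >= 2 replicates in >= 1 condition")
  mean_mat <- sapply(use_conds, function(cc) rowMeans(norm[, conditions == cc, drop = FALSE]))
  var_mat <- sapply(use_conds, function(cc) {
    x <- norm[, conditions == cc, drop = FALSE]
    rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  })
  mean_mat <- matrix(mean_mat, nrow = nrow(k))
  var_mat <- matrix(var_mat, nrow = nrow(k))
  w <- (reps[use_conds] - 1)
  mu <- as.vector(mean_mat %*% w / sum(w))
  v <- as.vector(var_mat %*% w / sum(w))
  a_raw <- pmax((v - mu) / mu^2, alpha_min)
  a_raw[!is.finite(a_raw)] <- alpha_min

  fit_on <- which(a_raw > alpha_min & mu > 0)
  if (length(fit_on) >= 10) {
    co <- stats::coef(stats::lm(log(a_raw[fit_on]) ~ log(mu[fit_on])))
  } else {
    co <- c(log(max(stats::median(a_raw), alpha_min)), 0)
  }
  a_tr <- pmax(exp(co[1] + co[2] * log(pmax(mu, 1e-8))), alpha_min)
  a <- exp((1 - shrink) * log(a_raw) + shrink * log(a_tr))
  a <- pmax(a, a_tr)
  a[v == 0] <- alpha_min
  a <- pmax(a, alpha_min)
  structure(stats::setNames(a, rownames(k)), trend = co)
}

#' NB Wald differential expression between two conditions
#'
#' Normalized group means feed a Wald statistic on the natural-log mean
#' ratio with delta-method standard error under NB(mean, alpha):
#' `Var(log mu_hat) = (1/mu + alpha) / n` per group. Reported `log2FC` uses a
#' pseudo-count of 0.5 on the normalized means (display only, not in the
#' statistic); group means are floored at 0.25 inside the statistic so
#' features expressed in a single group get a large finite Wald z rather than
#' an infinite one. All-zero features are flagged with p = 1 and log2FC = 0.
#' BH adjustment runs across all features in the matrix (one feature kind per
#' matrix), and `direction` applies `alpha` to the adjusted p (defaults:
#' 0.05 for genes, 0.1 for eRNAs).
#'
#' @param counts A [count_matrix()].
#' @param contrast Character pair `c(reference, alternative)`.
#' @param sf Size factors (default [size_factors()]).
#' @param dispersions Per-feature dispersions (default
#'   [estimate_dispersion()]).
#' @param alpha Significance level on `p_adj`; default by feature kind.
#' @param alpha_min,shrink Passed to [estimate_dispersion()] when
#'   dispersions are not supplied.
#' @return A `de_result` data.frame: `feature`, `baseMean`, `log2FC`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`, `direction` (`up`/`down`/`none`),
#'   `flag_zero`.
#' @export
nb_wald <- function(counts, contrast, sf = NULL, dispersions = NULL,
                    alpha = NULL, alpha_min = 1e-8, shrink = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  alpha <- alpha %||% if (counts$feature_kind == "gene") 0.05 else 0.1
  if (length(contrast) != 2) stopf("nb_wald: 'contrast' must be a pair of condition labels")
  cond <- counts$samples$condition
  missing_cond <- setdiff(contrast, cond)
  if (length(missing_cond)) {
    stopf("contrast error: unknown condition label(s): %s",
          paste(missing_cond, collapse = ", "))
  }
  s1 <- counts$samples$sample[cond == contrast[1]]
  s2 <- counts$samples$sample[cond == contrast[2]]
  if (length(s1) < 2 || length(s2) < 2) {
    stopf("nb_wald: both conditions need >= 2 replicates")
  }
  sf <- sf %||% size_factors(counts)
  dispersions <- dispersions %||%
    estimate_dispersion(counts, sf, alpha_min = alpha_min, shrink = shrink)
  k <- counts$counts
  if (!is.null(names(sf))) sf <- sf[colnames(k)]
  if (!is.null(names(dispersions))) dispersions <- dispersions[rownames(k)]
  norm <- sweep(k, 2, sf, "/")
  mu1 <- rowMeans(norm[, s1, drop = FALSE])
  mu2 <- rowMeans(norm[, s2, drop = FALSE])
  a <- as.numeric(dispersions)
  n1 <- length(s1)
  n2 <- length(s2)
  mu1s <- pmax(mu1, 0.25)
  mu2s <- pmax(mu2, 0.25)
  se <- sqrt((1 / mu1s + a) / n1 + (1 / mu2s + a) / n2)
  stat <- (log(mu2s) - log(mu1s)) / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  log2fc <- log2((mu2 + 0.5) / (mu1 + 0.5))
  zero <- mu1 == 0 & mu2 == 0
  stat[zero] <- 0
  pvalue[zero] <- 1
  log2fc[zero] <- 0
  padj <- bh_adjust(pvalue)
  direction <- rep("none", nrow(k))
  direction[padj < alpha & log2fc > 0] <- "up"
  direction[padj < alpha & log2fc < 0] <- "down"
  structure(data.frame(
    feature = rownames(k),
    baseMean = rowMeans(norm),
    log2FC = log2fc,
    lfcSE = se / log(2),
    stat = stat,
    pvalue = pvalue,
    padj = padj,
    direction = direction,
    flag_zero = zero,
    stringsAsFactors = FALSE
  ), class = c("de_result", "data.frame"),
  contrast = contrast, alpha = alpha, feature_kind = counts$feature_kind)
}

#' Simulate an NB count matrix with optional planted fold changes
#'
#' Two-group NB draws with log-uniform baseline means; the first
#' `n_de` features carry `log2fc` in the second group. Used for DE
#' calibration/power checks.
#'
#' @param n_features Number of features.
#' @param n_per_group Replicates per group.
#' @param mean_range Baseline mean range (log-uniform).
#' @param dispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param n_de Number of leading features with a planted change.
#' @param log2fc Planted log2 fold change for those features.
#' @param de_mean Baseline mean forced on planted features (`NULL` to draw).
#' @param seed Integer seed.
#' @return A list with a [count_matrix()] (`counts`), the group design, and
#'   `truth` (per-feature true log2FC).
#' @export
simulate_count_matrix <- function(n_features, n_per_group, mean_range = c(20, 500),
                                  dispersion = 0.05, n_de = 0, log2fc = 1,
                                  de_mean = NULL, seed = 1L) {
  with_seed(seed, {
    mu <- exp(stats::runif(n_features, log(mean_range[1]), log(mean_range[2])))
    if (n_de > 0 && !is.null(de_mean)) mu[seq_len(n_de)] <- de_mean
    mu2 <- mu
    if (n_de > 0) mu2[seq_len(n_de)] <- mu[seq_len(n_de)] * 2^log2fc
    draw <- function(m) {
      if (dispersion <= 0) matrix(stats::rpois(n_features * n_per_group, m),
                                  n_features, n_per_group)
      else matrix(stats::rnbinom(n_features * n_per_group, mu = m,
                                 size = 1 / dispersion),
                  n_features, n_per_group)
    }
    k <- cbind(draw(mu), draw(mu2))
    rownames(k) <- sprintf("f%05d", seq_len(n_features))
    design <- make_design(c("A", "B"), n_per_group)
    colnames(k) <- design$sample
    truth <- rep(0, n_features)
    if (n_de > 0) truth[seq_len(n_de)] <- log2fc
    list(counts = count_matrix(k, design, "gene"),
         design = design,
         truth = stats::setNames(truth, rownames(k)))
  })
}
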