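# 5mC/5hmC estimation from paired BS/oxBS arrays, delta-beta contrasts,
# differential calling, z-score standardization, and 5mC-5hmC
# anti-correlation.
#
# Convention used throughout: delta-beta and correlations are computed on the
# *unclipped* BS - oxBS difference (h_raw) to avoid censoring bias; the
# clipped/rescaled estimates are used only when reporting state levels.

#' Estimate 5mC and 5hmC from paired BS/oxBS beta matrices
#'
#' The BS assay reads 5mC + 5hmC and the oxBS assay 5mC only, so per probe
#' and sample `h_raw = beta_BS - beta_oxBS` (may be negative under noise) and
#' `m = beta_oxBS`. For state reporting, `h = max(h_raw, 0)` and, where
#' `m + h > 1`, both are jointly rescaled by `1 / (m + h)`; the number of
#' rescaled cells is counted. Missing values in either assay propagate.
#'
#' @param bs,oxbs Probe- and design-aligned [beta_matrix()] objects with
#'   assays `"BS"` and `"oxBS"`.
#' @return An object of class `methylome_estimate` with matrices `m` (raw
#'   oxBS 5mC), `h_raw`, `h` and `m_scaled` (clipped/rescaled state
#'   estimates), the sample sheet, and `n_rescaled`.
#' @export
estimate_5hmc <- function(bs, oxbs) {
  stopifnot(inherits(bs, "beta_matrix"), inherits(oxbs, "beta_matrix"))
  if (bs$assay != "BS" || oxbs$assay != "oxBS") {
    stopf("estimate_5hmc: expected assays BS and oxBS, got %s and %s",
          bs$assay, oxbs$assay)
  }
  if (!identical(rownames(bs$values), rownames(oxbs$values))) {
    off <- c(setdiff(rownames(bs$values), rownames(oxbs$values)),
             setdiff(rownames(oxbs$values), rownames(bs$values)))
    stopf("alignment error: BS and oxBS probe sets differ%s",
          if (length(off)) sprintf(" (e.g. %s)", paste(utils::head(off, 5), collapse = ", "))
          else " in order")
  }
  if (!identical(bs$samples$sample, oxbs$samples$sample) ||
      !identical(bs$samples$condition, oxbs$samples$condition)) {
    stopf("alignment error: BS and oxBS sample designs differ")
  }
  m <- oxbs$values
  h_raw <- bs$values - oxbs$values
  h <- pmax(h_raw, 0)
  tot <- m + h
  over <- which(tot > 1)
  m_scaled <- m
  if (length(over)) {
    m_scaled[over] <- m[over] / tot[over]
    h[over] <- h[over] / tot[over]
  }
  structure(list(m = m, h_raw = h_raw, h = h, m_scaled = m_scaled,
                 samples = bs$samples, n_rescaled = length(over)),
            class = "methylome_estimate")
}

#' @export
print.methylome_estimate <- function(x, ...) {
  cat(sprintf("methylome_estimate: %d probes x %d samples (%d cells rescaled)\n",
              nrow(x$m), ncol(x$m), x$n_rescaled))
  invisible(x)
}

welch_t_rows <- function(x1, x2) {
  n1 <- rowSums(!is.na(x1))
  n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE)
  m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * pmax(n1 - 1, 1)) + v2^2 / (n2^2 * pmax(n2 - 1, 1)))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- NA_real_
  p
}

#' Per-probe delta-beta between two conditions
#'
#' Computes `delta = mean(alt) - mean(ref)` per probe for each methylation
#' mark. From a [estimate_5hmc()] result the marks are `m` (5mC, the raw oxBS
#' beta) and `h` (5hmC, the raw unclipped BS - oxBS difference); from a
#' single [beta_matrix()] the single mark is `beta` (total methylation).
#' Group means are computed over the available (non-missing) replicates; a
#' probe with no observed value in either group gets `NA`. With
#' `test = "welch_t"` a per-probe two-sided Welch t-test is attached with
#' BH-adjusted p within each mark (requires >= 2 replicates per group).
#'
#' @param x A `methylome_estimate` or a `beta_matrix`.
#' @param contrast Character pair `c(reference, alternative)` of condition
#'   labels; `delta` is alternative minus reference.
#' @param test `"none"` or `"welch_t"`.
#' @return A `delta_beta_table`: data.frame with columns `probe`, `mark`,
#'   `mean_ref`, `mean_alt`, `delta`, `p`, `p_adj`, `call` (initialised to
#'   `"none"`; see [call_differential()]).
#' @export
delta_beta <- function(x, contrast, test = c("none", "welch_t")) {
  test <- match.arg(test)
  if (inherits(x, "methylome_estimate")) {
    marks <- list(m = x$m, h = x$h_raw)
    samples <- x$samples
  } else if (inherits(x, "beta_matrix")) {
    marks <- list(beta = x$values)
    samples <- x$samples
  } else {
    stopf("delta_beta: 'x' must be a methylome_estimate or beta_matrix")
  }
  if (length(contrast) != 2) stopf("delta_beta: 'contrast' must be a pair of condition labels")
  missing_cond <- setdiff(contrast, samples$condition)
  if (length(missing_cond)) {
    stopf("contrast error: unknown condition label(s): %s",
          paste(missing_cond, collapse = ", "))
  }
  c1 <- samples$sample[samples$condition == contrast[1]]
  c2 <- samples$sample[samples$condition == contrast[2]]
  if (test == "welch_t" && (length(c1) < 2 || length(c2) < 2)) {
    stopf("delta_beta: welch_t requires >= 2 replicates per group")
  }
  out <- lapply(names(marks), function(mk) {
    v <- marks[[mk]]
    x1 <- v[, c1, drop = FALSE]
    x2 <- v[, c2, drop = FALSE]
    ok1 <- rowSums(!is.na(x1)) >= 1
    ok2 <- rowSums(!is.na(x2)) >= 1
    m1 <- ifelse(ok1, rowMeans(x1, na.rm = TRUE), NA_real_)
    m2 <- ifelse(ok2, rowMeans(x2, na.rm = TRUE), NA_real_)
    p <- if (test == "welch_t") welch_t_rows(x1, x2) else NA_real_
    data.frame(probe = rownames(v), mark = mk, mean_ref = m1, mean_alt = m2,
               delta = m2 - m1, p = p,
               p_adj = if (test == "welch_t") bh_adjust(p) else NA_real_,
               call = "none", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("delta_beta_table", "data.frame"),
            contrast = contrast, test = test)
}

#' Call differential methylation from a delta-beta table
#'
#' `hyper` if `delta > effect_threshold`, `hypo` if
#' `delta < -effect_threshold` (strict inequalities, so a delta exactly at
#' the threshold is not called). When `alpha` is given, the call additionally
#' requires `p_adj < alpha`, which needs a test to have been run;
#' threshold-only mode supports duplicate designs without replication-based
#' tests.
#'
#' @param table A [delta_beta()] result.
#' @param effect_threshold Non-negative |delta-beta| threshold (default the
#'   0.05 convention used for differential 5hmC).
#' @param alpha Optional significance level applied to `p_adj`.
#' @return The table with its `call` column filled in.
#' @export
call_differential <- function(table, effect_threshold = 0.05, alpha = NULL) {
  stopifnot(inherits(table, "delta_beta_table"))
  if (effect_threshold < 0) stopf("call_differential: effect_threshold must be >= 0")
  if (!is.null(alpha) && all(is.na(table$p))) {
    stopf("configuration error: 'alpha' given but no test was run (use delta_beta(..., test = 'welch_t'))")
  }
  sig <- if (is.null(alpha)) TRUE else !is.na(table$p_adj) & table$p_adj < alpha
  call <- rep("none", nrow(table))
  call[!is.na(table$delta) & table$delta > effect_threshold & sig] <- "hyper"
  call[!is.na(table$delta) & table$delta < -effect_threshold & sig] <- "hypo"
  table$call <- call
  attr(table, "effect_threshold") <- effect_threshold
  attr(table, "alpha") <- alpha
  table
}

#' Pearson anti-correlation between 5hmC and 5mC changes
#'
#' Correlates per-probe delta-beta of one mark against another over a probe
#' selection (typically the differentially hydroxymethylated probes), the
#' statistic used to show that 5hmC gain is mirrored by 5mC loss.
#'
#' @param table_h A [delta_beta()] table, or a combined table carrying both
#'   marks (in which case `table_m` may be `NULL`).
#' @param table_m Optional second table; defaults to the `m` rows of
#'   `table_h`.
#' @param probes Probe ids to restrict to (>= 3 required); `NULL` uses all
#'   probes present in both tables.
#' @param marks Pair of mark labels drawn from the tables (first from
#'   `table_h`, second from `table_m`).
#' @return A list with `r` (Pearson correlation), `n`, and the mark pair.
#' @export
correlate_changes <- function(table_h, table_m = NULL, probes = NULL,
                              marks = c("h", "m")) {
  stopifnot(inherits(table_h, "delta_beta_table"))
  table_m <- table_m %||% table_h
  th <- table_h[table_h$mark == marks[1], , drop = FALSE]
  tm <- table_m[table_m$mark == marks[2], , drop = FALSE]
  if (!nrow(th) || !nrow(tm)) {
    stopf("correlate_changes: mark(s) %s absent from table(s)",
          paste(marks, collapse = "/"))
  }
  common <- intersect(th$probe, tm$probe)
  if (!is.null(probes)) common <- intersect(common, probes)
  common <- common[!is.na(th$delta[match(common, th$probe)]) &
                     !is.na(tm$delta[match(common, tm$probe)])]
  if (length(common) < 3) stopf("correlate_changes: fewer than 3 probes in selection")
  x <- th$delta[match(common, th$probe)]
  y <- tm$delta[match(common, tm$probe)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("undefined-correlation error: zero variance in one coordinate")
  }
  list(r = stats::cor(x, y), n = length(common), marks = marks)
}

#' Row-wise z-score standardization of probe profiles
#'
#' Standardizes each probe's vector across conditions to mean 0 and unit
#' variance (sample sd, n - 1), the transform used for heat-map display of
#' delta-beta profiles. Constant rows become all zeros and are flagged.
#'
#' @param values Numeric matrix, probes x conditions (>= 2 columns).
#' @return A list with `z` (the standardized matrix) and `constant` (logical
#'   per row).
#' @export
standardize_profiles <- function(values) {
  stopifnot(is.matrix(values))
  if (ncol(values) < 2) stopf("standardize_profiles: need >= 2 conditions")
  mu <- rowMeans(values, na.rm = TRUE)
  sd <- apply(values, 1, stats::sd, na.rm = TRUE)
  constant <- !is.finite(sd) | sd == 0
  z <- (values - mu) / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  list(z = z, constant = constant)
}
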