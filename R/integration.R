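# Integrative analyses: enhancer-promoter pairing within a distance window,
# hypergeometric overlap tests, preranked GSEA, and methylation-retention
# summaries over probe sets.

#' Pair differential enhancers with co-regulated promoters
#'
#' All (enhancer, gene) pairs whose enhancer midpoint lies within `window` bp
#' of the gene's strand-aware TSS, among features significant in their
#' respective differential tables. Concordance means matching up/down
#' direction; one enhancer may pair with several genes and vice versa.
#'
#' @param de_ernas A `de_result` for eRNAs (or any data.frame with `feature`
#'   and `direction`).
#' @param erna_loc data.frame with `id` (or `feature`), `chrom`, `start`,
#'   `end` (0-based half-open) locating each eRNA.
#' @param de_genes A `de_result` for genes.
#' @param tss data.frame with `gene`, `chrom`, `tss` (1-based), e.g. from the
#'   genome annotation.
#' @param window Maximum |midpoint - TSS| distance (bp); default 500 kb.
#' @param require_concordant Keep only direction-concordant pairs.
#' @return data.frame of links: `enhancer`, `gene`, `distance` (signed,
#'   midpoint to TSS), `dir_enhancer`, `dir_gene`, `concordant`.
#' @export
pair_enhancer_promoter <- function(de_ernas, erna_loc, de_genes, tss,
                                   window = 5e5, require_concordant = TRUE) {
  if (window < 0) stopf("pair_enhancer_promoter: 'window' must be >= 0")
  idcol <- if ("id" %in% names(erna_loc)) "id" else "feature"
  e_sig <- de_ernas[de_ernas$direction != "none", , drop = FALSE]
  g_sig <- de_genes[de_genes$direction != "none", , drop = FALSE]
  empty <- data.frame(enhancer = character(0), gene = character(0),
                      distance = numeric(0), dir_enhancer = character(0),
                      dir_gene = character(0), concordant = logical(0))
  if (!nrow(e_sig) || !nrow(g_sig)) return(empty)
  loc <- erna_loc[match(e_sig$feature, erna_loc[[idcol]]), , drop = FALSE]
  keep <- !is.na(loc$chrom)
  e_sig <- e_sig[keep, , drop = FALSE]
  loc <- loc[keep, , drop = FALSE]
  if (!nrow(e_sig)) return(empty)
  mid <- midpoint0(loc$start, loc$end)
  gloc <- tss[match(g_sig$feature, tss$gene), , drop = FALSE]
  rows <- lapply(seq_len(nrow(e_sig)), function(i) {
    same <- which(gloc$chrom == loc$chrom[i] &
                    abs((gloc$tss - 1) - mid[i]) <= window)
    if (!length(same)) return(NULL)
    data.frame(enhancer = e_sig$feature[i],
               gene = g_sig$feature[same],
               distance = (gloc$tss[same] - 1) - mid[i],
               dir_enhancer = e_sig$direction[i],
               dir_gene = g_sig$direction[same],
               concordant = e_sig$direction[i] == g_sig$direction[same],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  if (require_concordant) out <- out[out$concordant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap test between two id sets
#'
#' Upper-tail probability P(X >= k) of observing at least the seen overlap k
#' between sets of sizes |A| and |B| drawn from a universe of size N
#' (X ~ Hypergeometric(N, |A|, |B|)). The universe is an explicit, required
#' parameter.
#'
#' @param a,b Id vectors; both must be subsets of `universe`.
#' @param universe Background id vector (nonempty).
#' @return List of class `overlap_test`: `n_a`, `n_b`, `overlap`,
#'   `universe`, `p` (with `degenerate = TRUE` flagged when A = B =
#'   universe).
#' @export
overlap_test <- function(a, b, universe) {
  if (!length(universe)) stopf("overlap_test: empty universe")
  universe <- unique(universe)
  a <- unique(a)
  b <- unique(b)
  if (length(setdiff(a, universe)) || length(setdiff(b, universe))) {
    stopf("overlap_test: sets must be subsets of the universe")
  }
  k <- length(intersect(a, b))
  p <- min(1, hyper_tail(k, length(a), length(universe), length(b), upper = TRUE))
  structure(list(n_a = length(a), n_b = length(b), overlap = k,
                 universe = length(universe), p = p,
                 degenerate = length(a) == length(universe) &&
                   length(b) == length(universe)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap_test: |A|=%d, |B|=%d, overlap=%d, N=%d, P(X>=k)=%.3g%s\n",
              x$n_a, x$n_b, x$overlap, x$universe, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

gsea_es <- function(ord_scores, in_set, weight = 1) {
  N <- length(ord_scores)
  n_set <- sum(in_set)
  w <- abs(ord_scores)^weight
  denom <- sum(w[in_set])
  inc <- ifelse(in_set, if (denom > 0) w / denom else 1 / n_set,
                -1 / (N - n_set))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment (weighted running-sum)
#'
#' Genes are ordered by decreasing score; the running sum increments at set
#' hits proportionally to |score|^`weight` (normalized over set hits) and
#' decrements 1/(N - n_set) at misses; the enrichment score ES is the running
#' sum at its maximum deviation. Significance comes from gene-label
#' permutations (random same-size sets): NES = ES divided by the mean |ES|
#' of same-sign permutations, and the p-value is the +1-smoothed fraction of
#' same-sign permutations at least as extreme.
#'
#' @param scores Named numeric vector (gene-level ranking statistic);
#'   names must be unique.
#' @param gene_set Character vector of gene ids; must intersect the ranking.
#' @param n_perm Number of permutations.
#' @param weight Hit-increment exponent on |score| (1 = standard weighting;
#'   0 = classical Kolmogorov-Smirnov).
#' @param seed Integer seed for the permutations.
#' @return A list of class `gsea_result`: `es`, `nes`, `p`, `n_perm`,
#'   `n_set` (set genes present in the ranking), `seed`.
#' @export
preranked_gsea <- function(scores, gene_set, n_perm = 1000, weight = 1,
                           seed = 1L) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stopf("preranked_gsea: 'scores' must be uniquely named")
  }
  present <- intersect(gene_set, names(scores))
  if (!length(present)) stopf("preranked_gsea: gene set disjoint from the ranking")
  if (length(present) >= length(scores)) {
    stopf("preranked_gsea: gene set covers the whole ranking")
  }
  ord <- order(-scores, names(scores))
  s <- as.numeric(scores)[ord]
  in_set <- names(scores)[ord] %in% present
  es <- gsea_es(s, in_set, weight)
  perm_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(s), length(present))
    gsea_es(s, seq_along(s) %in% idx, weight)
  }, numeric(1)))
  same <- perm_es[sign(perm_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(es = es, nes = nes, p = p, n_perm = n_perm,
                 n_set = length(present), seed = seed),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES=%.3f, NES=%.3f, p=%.3g (%d genes, %d perms)\n",
              x$es, x$nes, x$p, x$n_set, x$n_perm))
  invisible(x)
}

#' Methylation retention over a probe set
#'
#' Per-probe group-mean delta-beta (treated minus baseline) over a probe set;
#' a probe is "retained" when |delta| stays below the retention threshold
#' (the 0.05 delta-beta convention). Used to show that HLA-like cluster
#' probes keep their hypermethylation after treatment while the global
#' differential set reverses.
#'
#' @param baseline,treated [beta_matrix()] objects sharing the probe set
#'   (e.g. the same BS matrix subset to different conditions).
#' @param probe_set Probe ids; all must be present in both matrices.
#' @param retention_threshold |delta-beta| below which a probe counts as
#'   retained.
#' @return A list of class `retention_summary`: `n`, `mean_baseline`,
#'   `mean_treated`, `mean_delta`, `retained_fraction`, `delta` (per probe).
#' @export
methylation_retention <- function(baseline, treated, probe_set,
                                  retention_threshold = 0.05) {
  stopifnot(inherits(baseline, "beta_matrix"), inherits(treated, "beta_matrix"))
  miss <- c(setdiff(probe_set, rownames(baseline$values)),
            setdiff(probe_set, rownames(treated$values)))
  if (length(miss)) {
    stopf("methylation_retention: %d probe(s) missing from the matrices: %s",
          length(unique(miss)),
          paste(utils::head(unique(miss), 5), collapse = ", "))
  }
  b <- rowMeans(baseline$values[probe_set, , drop = FALSE], na.rm = TRUE)
  t <- rowMeans(treated$values[probe_set, , drop = FALSE], na.rm = TRUE)
  delta <- t - b
  structure(list(n = length(probe_set),
                 mean_baseline = mean(b), mean_treated = mean(t),
                 mean_delta = mean(delta),
                 retained_fraction = mean(abs(delta) < retention_threshold),
                 delta = delta),
            class = "retention_summary")
}

#' @export
print.retention_summary <- function(x, ...) {
  cat(sprintf("retention_summary: %d probes, mean delta %.3f, retained %.1f%%\n",
              x$n, x$mean_delta, 100 * x$retained_fraction))
  invisible(x)
}
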