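# Independent brute-force oracles used to validate the package's statistics.
# These deliberately use naive loop/enumeration implementations, not the
# code paths they check.

# Upper-tail hypergeometric by explicit choose() enumeration.
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  kk <- kk[kk >= max(0, n - (N - K))]
  if (!length(kk)) return(0)
  sum(vapply(kk, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

oracle_hyper_lower <- function(k, K, N, n) {
  kk <- max(0, n - (N - K)):min(k, K, n)
  if (!length(kk) || kk[1] > min(k, K, n)) return(0)
  sum(vapply(kk, function(x) {
    choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }, numeric(1)))
}

# Single-pass scan segmentation oracle: walk the bins, collect runs >= tau,
# merge across small gaps, apply the length filter.
oracle_segment <- function(x, tau, gap_bp, min_len_bp, bin_size) {
  runs <- list()
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (x[i] >= tau) {
      j <- i
      while (j < n && x[j + 1] >= tau) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(runs)) return(data.frame(start = numeric(0), end = numeric(0)))
  gap_bins <- floor(gap_bp / bin_size)
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= gap_bins) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else {
      merged[[length(merged) + 1]] <- r
    }
  }
  out <- do.call(rbind, lapply(merged, function(r) {
    data.frame(start = (r[1] - 1) * bin_size, end = r[2] * bin_size)
  }))
  out[(out$end - out$start) >= min_len_bp, , drop = FALSE]
}

# Brute-force BH step-up by definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  adj
}

# All-pairs enhancer-promoter filter.
oracle_ep_pairs <- function(enh, genes, window, require_concordant) {
  rows <- list()
  for (i in seq_len(nrow(enh))) {
    for (j in seq_len(nrow(genes))) {
      if (enh$chrom[i] != genes$chrom[j]) next
      mid <- floor((enh$start[i] + enh$end[i]) / 2)
      d <- (genes$tss[j] - 1) - mid
      if (abs(d) > window) next
      conc <- enh$direction[i] == genes$direction[j]
      if (require_concordant && !conc) next
      rows[[length(rows) + 1]] <- data.frame(
        enhancer = enh$id[i], gene = genes$gene[j], distance = d,
        concordant = conc, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(enhancer = character(0), gene = character(0),
                      distance = numeric(0), concordant = logical(0)))
  }
  do.call(rbind, rows)
}

# Literal running-sum GSEA enrichment score.
oracle_gsea_es <- function(scores, set, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% set
  nh <- sum(hit)
  N <- length(s)
  denom <- sum(abs(s[hit])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(s[i])^weight / denom else -1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
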