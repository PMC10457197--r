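# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded generator calls never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One global seed expands into named per-stage substreams, in a fixed
# documented order, so stages can be regenerated independently.
STAGE_SEED_ORDER <- c("genome", "methylome", "transcription", "motifs", "gsea")

derive_seeds <- function(seed, labels = STAGE_SEED_ORDER) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(labels)))
  names(s) <- labels
  s
}

# Exact hypergeometric tail probabilities, shared by feature_enrichment,
# integration::overlap_test and motifs. X ~ Hypergeometric(N, K, n): number of
# "in-class" elements among n drawn from a universe of N containing K in-class.
hyper_tail <- function(k, K, N, n, upper = TRUE) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= K, N >= n)
  if (upper) {
    lo <- k
    hi <- min(K, n)
    if (lo > hi) return(0)
    sum(stats::dhyper(lo:hi, K, N - K, n))
  } else {
    hi <- min(k, K, n)
    lo <- max(0, n - (N - K))
    if (hi < lo) return(0)
    sum(stats::dhyper(lo:hi, K, N - K, n))
  }
}

# 2x2 enrichment: a = selected & in-class, with selected of size n_sel from a
# universe of size N containing K in-class elements.
fisher_one_sided <- function(a, n_sel, K, N) {
  list(
    p_greater = min(1, hyper_tail(a, K, N, n_sel, upper = TRUE)),
    p_less = min(1, hyper_tail(a, K, N, n_sel, upper = FALSE))
  )
}

# Interval midpoints on 0-based half-open coordinates.
midpoint0 <- function(start, end) floor((start + end) / 2)
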