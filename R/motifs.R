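# PWM scanning of promoter/enhancer sequences and sequence-level motif
# enrichment (percentage of target sequences with a motif, Fisher exact vs a
# background set), plus seeded synthetic-sequence utilities for validation.

DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' @param mat Numeric matrix, positions x bases (columns A, C, G, T), each
#'   row summing to 1 (within 1e-9); at least 4 positions.
#' @param id Motif id.
#' @param pseudocount Probability pseudocount mixed in before log-odds.
#' @param background Named base frequencies (default uniform).
#' @return An object of class `pwm` with the log2-odds `score_matrix` and
#'   `max_score` (sum of positionwise maxima) precomputed.
#' @export
pwm <- function(mat, id = "motif", pseudocount = 1e-3,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stopf("pwm: matrix must have 4 columns (A, C, G, T)")
  colnames(mat) <- DNA_BASES
  if (nrow(mat) < 4) stopf("pwm: motif length must be >= 4")
  if (any(abs(rowSums(mat) - 1) > 1e-9)) stopf("pwm: each position must sum to 1")
  if (any(mat < 0)) stopf("pwm: probabilities must be >= 0")
  background <- background[DNA_BASES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6) {
    stopf("pwm: background must be frequencies over A, C, G, T summing to 1")
  }
  p <- (mat + pseudocount) / (1 + 4 * pseudocount)
  S <- log2(sweep(p, 2, background, "/"))
  structure(list(id = id, mat = mat, pseudocount = pseudocount,
                 background = background, score_matrix = S,
                 max_score = sum(apply(S, 1, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': %d positions, consensus %s, max score %.2f bits\n",
              x$id, nrow(x$mat), consensus(x), x$max_score))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x A [pwm()].
#' @return Character string of the per-position argmax bases.
#' @export
consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$mat, 1, which.max)], collapse = "")
}

encode_seq <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], DNA_BASES)
  v # NA for N / other characters
}

scan_one <- function(enc, S, L) {
  nw <- length(enc) - L + 1
  if (nw < 1) return(numeric(0))
  sc <- numeric(nw)
  for (j in seq_len(L)) {
    v <- S[j, ][enc[j:(j + nw - 1)]]
    v[is.na(v)] <- 0 # N scores as background
    sc <- sc + v
  }
  sc
}

#' Scan sequences with a PWM on both strands
#'
#' Windows score as the sum of position log2-odds (bases outside A/C/G/T
#' contribute 0, i.e. background); a window is a hit when its score reaches
#' `score_fraction` of the maximal achievable score. Both strands are
#' scanned; presence means at least one hit on either strand.
#'
#' @param seqs Named character vector (or `Biostrings::DNAStringSet`) of
#'   sequences over A/C/G/T/N.
#' @param pwm A [pwm()].
#' @param score_fraction Hit threshold as a fraction of the maximal score,
#'   in (0, 1\].
#' @return List with `hits` (data.frame: `seq`, `pos` 1-based on the input
#'   strand's forward coordinates, `strand`, `score`), `presence` (named
#'   logical), and `short` (sequences shorter than the motif, flagged).
#' @export
scan_sequences <- function(seqs, pwm, score_fraction = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  if (score_fraction <= 0 || score_fraction > 1) {
    stopf("scan_sequences: 'score_fraction' must be in (0, 1]")
  }
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (pwm$max_score <= 0) stopf("scan_sequences: degenerate PWM (max score <= 0)")
  # Small slack so score_fraction = 1 still accepts exact-consensus windows
  # despite floating-point summation order.
  thr <- score_fraction * pwm$max_score - 1e-9
  S <- pwm$score_matrix
  L <- nrow(S)
  hits <- list()
  presence <- stats::setNames(logical(length(seqs)), names(seqs))
  short <- character(0)
  for (nm in names(seqs)) {
    enc <- encode_seq(seqs[[nm]])
    if (length(enc) < L) {
      short <- c(short, nm)
      next
    }
    fw <- scan_one(enc, S, L)
    rc <- scan_one(rev(5L - enc), S, L)
    hf <- which(fw >= thr)
    hr <- which(rc >= thr)
    presence[nm] <- length(hf) > 0 || length(hr) > 0
    if (length(hf)) {
      hits[[length(hits) + 1]] <- data.frame(
        seq = nm, pos = hf, strand = "+", score = fw[hf],
        stringsAsFactors = FALSE)
    }
    if (length(hr)) {
      # Position of the hit window on the forward strand.
      hits[[length(hits) + 1]] <- data.frame(
        seq = nm, pos = length(enc) - (hr + L - 1) + 1, strand = "-",
        score = rc[hr], stringsAsFactors = FALSE)
    }
  }
  list(hits = if (length(hits)) do.call(rbind, hits) else
    data.frame(seq = character(0), pos = integer(0),
               strand = character(0), score = numeric(0)),
    presence = presence, short = short)
}

#' Motif enrichment of target vs background sequences
#'
#' Sequence-level presence counting (does a sequence contain at least one
#' hit), a 2x2 Fisher one-sided (greater) test per motif against the
#' background set, and BH adjustment across motifs; sorted by p. With no
#' background, a seeded mononucleotide shuffle of the targets is used.
#'
#' @param targets,background Named character vectors of sequences;
#'   `background = NULL` shuffles the targets.
#' @param pwms List of [pwm()] objects.
#' @param score_fraction Passed to [scan_sequences()].
#' @param seed Seed for the background shuffle.
#' @return data.frame: `motif`, `pct_targets`, `pct_background`,
#'   `n_targets`, `n_background`, `p`, `p_adj`, sorted by `p`.
#' @export
motif_enrichment <- function(targets, background = NULL, pwms,
                             score_fraction = 0.8, seed = 1L) {
  if (!length(targets)) stopf("motif_enrichment: empty target set")
  if (!length(pwms)) {
    return(data.frame(motif = character(0), pct_targets = numeric(0),
                      pct_background = numeric(0), n_targets = integer(0),
                      n_background = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  background <- background %||% shuffle_sequences(targets, seed = seed)
  if (!length(background)) stopf("motif_enrichment: empty background set")
  rows <- lapply(pwms, function(pw) {
    pt <- scan_sequences(targets, pw, score_fraction)$presence
    pb <- scan_sequences(background, pw, score_fraction)$presence
    a <- sum(pt)
    # Universe = targets + background; class = "contains motif".
    p <- fisher_one_sided(a, length(pt), a + sum(pb),
                          length(pt) + length(pb))$p_greater
    data.frame(motif = pw$id,
               pct_targets = 100 * mean(pt),
               pct_background = 100 * mean(pb),
               n_targets = length(pt), n_background = length(pb),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, -out$pct_targets, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random i.i.d. DNA sequences
#'
#' @param n Number of sequences.
#' @param width Sequence length (bp).
#' @param gc GC content (A/T and G/C split evenly).
#' @param seed Integer seed.
#' @return Named character vector (`s0001`, ...).
#' @export
random_sequences <- function(n, width, gc = 0.41, seed = 1L) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    out <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, width, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
    names(out) <- sprintf("s%04d", seq_len(n))
    out
  })
}

#' Mononucleotide shuffle of sequences
#'
#' @param seqs Named character vector.
#' @param seed Integer seed.
#' @return Shuffled sequences (same names, `_shuf` suffix).
#' @export
shuffle_sequences <- function(seqs, seed = 1L) {
  with_seed(seed, {
    out <- vapply(seqs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1))
    names(out) <- paste0(names(seqs), "_shuf")
    out
  })
}

#' Plant a motif occurrence into a fraction of sequences
#'
#' Replaces a random window of each chosen sequence with the motif consensus
#' (forward strand).
#'
#' @param seqs Named character vector.
#' @param motif A [pwm()] or a consensus string.
#' @param fraction Fraction of sequences receiving an occurrence.
#' @param seed Integer seed.
#' @return The sequences with occurrences planted; attribute `planted` lists
#'   the modified names.
#' @export
plant_motif <- function(seqs, motif, fraction = 1, seed = 1L) {
  cons <- if (inherits(motif, "pwm")) consensus(motif) else as.character(motif)
  L <- nchar(cons)
  with_seed(seed, {
    chosen <- names(seqs)[sample.int(length(seqs), round(fraction * length(seqs)))]
    for (nm in chosen) {
      n <- nchar(seqs[[nm]])
      if (n < L) next
      at <- sample.int(n - L + 1, 1)
      substr(seqs[[nm]], at, at + L - 1) <- cons
    }
    attr(seqs, "planted") <- chosen
    seqs
  })
}

#' Random decoy PWMs
#'
#' Moderately peaked random PWMs (Dirichlet-like columns), usable as decoys
#' in enrichment validation.
#'
#' @param n Number of PWMs.
#' @param length Motif length.
#' @param seed Integer seed.
#' @param sharpness Gamma shape; smaller is more peaked.
#' @return Named list of [pwm()] objects (`decoy01`, ...).
#' @export
random_pwms <- function(n, length = 8, seed = 1L, sharpness = 0.3) {
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      g <- matrix(stats::rgamma(length * 4, sharpness), length, 4)
      pwm(g / rowSums(g), id = sprintf("decoy%02d", i))
    })
    names(out) <- vapply(out, `[[`, character(1), "id")
    out
  })
}

#' Read PWMs from a simple text format
#'
#' One matrix per motif: a header line `>id`, then one row of 4
#' whitespace-separated probabilities (A C G T) per position.
#'
#' @param path File path.
#' @return Named list of [pwm()] objects.
#' @export
read_pwms <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stopf("read_pwms: no '>' headers in %s", path)
  bounds <- c(heads, length(lines) + 1)
  out <- lapply(seq_along(heads), function(i) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    body <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    mat <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    pwm(mat, id = id)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write PWMs in the simple text format
#'
#' @param pwms Named list of [pwm()] objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pw in pwms) {
    writeLines(paste0(">", pw$id), con)
    writeLines(apply(pw$mat, 1, function(r) {
      paste(sprintf("%.17g", r), collapse = "\t")
    }), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
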