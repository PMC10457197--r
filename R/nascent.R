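# Strand-specific nascent-transcription coverage: binned tracks, pooled
# segmentation into transcribed units, eRNA classification with bidirectional
# merging, and unit quantification.

#' Binned strand-specific coverage for a set of samples
#'
#' @param values Nested list `values[[sample]][[strand]][[chrom]]` of per-bin
#'   counts, strands `"+"` and `"-"`; bins tile each chromosome.
#' @param bin_size Bin width (bp).
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param samples Sample sheet (`sample`, `condition`, `replicate`).
#' @return An object of class `coverage_set`.
#' @export
coverage_set <- function(values, bin_size, chrom_lengths, samples) {
  samples <- validate_sample_sheet(samples)
  if (!setequal(names(values), samples$sample)) {
    stopf("coverage_set: track names do not match sample sheet")
  }
  nbins <- ceiling(chrom_lengths / bin_size)
  for (s in samples$sample) {
    for (st in c("+", "-")) {
      tr <- values[[s]][[st]]
      if (!setequal(names(tr), names(chrom_lengths))) {
        stopf("coverage_set: sample %s strand %s misses chromosomes", s, st)
      }
      for (ch in names(tr)) {
        if (length(tr[[ch]]) != nbins[[ch]]) {
          stopf("coverage_set: %s/%s/%s has %d bins, expected %d",
                s, st, ch, length(tr[[ch]]), nbins[[ch]])
        }
        if (any(tr[[ch]] < 0)) stopf("coverage_set: negative coverage in %s/%s/%s", s, st, ch)
      }
    }
  }
  structure(list(values = values, bin_size = bin_size,
                 chrom_lengths = chrom_lengths, samples = samples),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("coverage_set: %d samples, %d chroms, bin %d bp\n",
              nrow(x$samples), length(x$chrom_lengths), x$bin_size))
  invisible(x)
}

#' Pool coverage across samples
#'
#' @param cs A [coverage_set()].
#' @param samples Sample ids to pool (default all). Units are annotated on
#'   pooled coverage so the annotation is not biased toward any condition.
#' @return List `pooled[[strand]][[chrom]]` of summed tracks, with attribute
#'   `n_tracks` (number of samples pooled).
#' @export
pool_coverage <- function(cs, samples = NULL) {
  stopifnot(inherits(cs, "coverage_set"))
  samples <- samples %||% cs$samples$sample
  out <- lapply(c("+", "-"), function(st) {
    lapply(stats::setNames(nm = names(cs$chrom_lengths)), function(ch) {
      Reduce(`+`, lapply(samples, function(s) cs$values[[s]][[st]][[ch]]))
    })
  })
  names(out) <- c("+", "-")
  attr(out, "n_tracks") <- length(samples)
  out
}

#' Segmentation parameters
#'
#' @param tau Coverage threshold (per-bin, on the segmented track). `NULL`
#'   resolves to `max(3, ceiling(0.75 * n_tracks))` for pooled tracks -- a
#'   fixed depth-scaled threshold chosen so that isolated background bins
#'   cannot chain through the merge gap into length-passing segments;
#'   `"q90"` uses the 90th percentile of nonzero bins instead
#'   (data-dependent; unstable when transcribed bins are a non-negligible
#'   share of nonzero bins, see the methods vignette).
#' @param gap Maximum sub-threshold gap (bp) merged into a run.
#' @param min_len Minimum merged run length (bp); shorter runs are dropped.
#' @param d_ex Genic exclusion margin (bp): units overlapping a gene extended
#'   by `d_ex` on both sides are genic, never eRNA.
#' @param d_pair Maximum distance (bp) between opposite-strand intergenic
#'   units merged into one bidirectional eRNA.
#' @return An object of class `segment_params`.
#' @export
segment_params <- function(tau = NULL, gap = 200, min_len = 200,
                           d_ex = 1000, d_pair = 1000) {
  if (!is.null(tau) && !identical(tau, "q90")) {
    tau <- as.numeric(tau)
    if (!is.finite(tau) || tau <= 0) stopf("segment_params: 'tau' must be > 0")
  }
  for (v in c(gap, min_len, d_ex, d_pair)) {
    if (!is.finite(v) || v < 0) stopf("segment_params: gap/min_len/d_ex/d_pair must be >= 0")
  }
  structure(list(tau = tau, gap = gap, min_len = min_len,
                 d_ex = d_ex, d_pair = d_pair), class = "segment_params")
}

resolve_tau <- function(params, pooled) {
  if (is.numeric(params$tau)) return(params$tau)
  if (identical(params$tau, "q90")) {
    vals <- unlist(lapply(pooled, function(st) lapply(st, function(x) x[x > 0])),
                   use.names = FALSE)
    if (!length(vals)) return(1)
    return(max(1, stats::quantile(vals, 0.9, names = FALSE)))
  }
  max(3, ceiling(0.75 * (attr(pooled, "n_tracks") %||% 1)))
}

#' Segment one coverage track into transcribed intervals
#'
#' Maximal runs of bins with value >= `tau`; runs separated by at most `gap`
#' bp of sub-threshold signal are merged; merged runs shorter than `min_len`
#' bp are discarded. Output intervals are sorted, non-overlapping, 0-based
#' half-open, aligned to bin boundaries.
#'
#' @param x Numeric per-bin coverage vector for one chromosome/strand.
#' @param params A [segment_params()] with numeric `tau`.
#' @param bin_size Bin width (bp).
#' @return data.frame with columns `start`, `end` (bp, 0-based half-open).
#' @export
segment_coverage <- function(x, params, bin_size = 10L) {
  stopifnot(inherits(params, "segment_params"), is.numeric(params$tau))
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (!length(x)) return(empty)
  above <- x >= params$tau
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ti <- which(r$values)
  rs <- starts[ti]
  re <- ends[ti]
  gap_bins <- floor(params$gap / bin_size)
  if (length(ti) > 1) {
    gaps <- rs[-1] - re[-length(re)] - 1
    grp <- cumsum(c(1, gaps > gap_bins))
  } else {
    grp <- 1
  }
  ms <- tapply(rs, grp, min)
  me <- tapply(re, grp, max)
  len_bp <- (me - ms + 1) * bin_size
  keep <- len_bp >= params$min_len
  if (!any(keep)) return(empty)
  data.frame(start = (ms[keep] - 1) * bin_size, end = me[keep] * bin_size,
             row.names = NULL)
}

segments_to_gr <- function(df, chrom, chrom_lengths, strand = "*") {
  if (!nrow(df)) {
    return(GenomicRanges::GRanges(seqlengths = chrom_lengths))
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(df$start + 1, df$end),
                         strand = strand, seqlengths = chrom_lengths)
}

#' Classify segmented intervals into genic / eRNA / other units
#'
#' Intervals overlapping any gene extended by `d_ex` bp are genic. Remaining
#' (intergenic) intervals on opposite strands lying within `d_pair` bp of
#' each other are merged into one bidirectional eRNA spanning their union
#' (greedy nearest pairing, each interval used once, deterministic order).
#' Unpaired intergenic intervals are eRNAs if at least `min_len` bp, else
#' `other`. Unit ids are deterministic (`eRNA.<chrom>:<start>-<end>` on
#' 0-based half-open coordinates).
#'
#' @param segments List with elements `"+"` and `"-"`, each a data.frame of
#'   `chrom`, `start`, `end` (0-based half-open) as from
#'   [segment_coverage()].
#' @param annotation A [build_genome()] annotation (uses `genes` and
#'   `chrom_lengths`).
#' @param params A [segment_params()].
#' @return data.frame of units: `id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`*` for merged eRNAs), `class`, `src_plus`,
#'   `src_minus` (source interval keys for merged units).
#' @export
classify_units <- function(segments, annotation, params = segment_params()) {
  chrom_lengths <- annotation$chrom_lengths
  mk <- function(st) {
    df <- segments[[st]]
    if (is.null(df) || !nrow(df)) {
      return(data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0)))
    }
    data.frame(chrom = df$chrom, start = df$start, end = df$end, strand = st,
               stringsAsFactors = FALSE)
  }
  segs <- rbind(mk("+"), mk("-"))
  if (!nrow(segs)) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), class = character(0),
                      src_plus = character(0), src_minus = character(0)))
  }
  gr <- GenomicRanges::GRanges(segs$chrom,
                               IRanges::IRanges(segs$start + 1, segs$end),
                               seqlengths = chrom_lengths)
  genes_ext <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::granges(annotation$genes) + params$d_ex))
  genic <- IRanges::overlapsAny(gr, genes_ext, ignore.strand = TRUE)
  key <- sprintf("%s:%d-%d", segs$chrom, segs$start, segs$end)

  ip <- which(!genic & segs$strand == "+")
  im <- which(!genic & segs$strand == "-")
  pair_of <- rep(NA_integer_, nrow(segs))
  if (length(ip) && length(im)) {
    hits <- GenomicRanges::findOverlaps(gr[ip], gr[im],
                                        maxgap = params$d_pair,
                                        ignore.strand = TRUE)
    if (length(hits)) {
      qi <- ip[S4Vectors::queryHits(hits)]
      si <- im[S4Vectors::subjectHits(hits)]
      dd <- GenomicRanges::distance(gr[qi], gr[si], ignore.strand = TRUE)
      ord <- order(dd, segs$start[qi], segs$start[si])
      used <- logical(nrow(segs))
      for (j in ord) {
        a <- qi[j]; b <- si[j]
        if (!used[a] && !used[b]) {
          used[a] <- used[b] <- TRUE
          pair_of[a] <- b
          pair_of[b] <- a
        }
      }
    }
  }
  rows <- list()
  done <- logical(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (done[i]) next
    if (genic[i]) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = segs$chrom[i], start = segs$start[i], end = segs$end[i],
        strand = segs$strand[i], class = "genic",
        src_plus = if (segs$strand[i] == "+") key[i] else NA_character_,
        src_minus = if (segs$strand[i] == "-") key[i] else NA_character_,
        stringsAsFactors = FALSE)
      done[i] <- TRUE
    } else if (!is.na(pair_of[i])) {
      j <- pair_of[i]
      a <- if (segs$strand[i] == "+") i else j
      b <- if (segs$strand[i] == "+") j else i
      rows[[length(rows) + 1]] <- data.frame(
        chrom = segs$chrom[i],
        start = min(segs$start[c(i, j)]), end = max(segs$end[c(i, j)]),
        strand = "*", class = "eRNA",
        src_plus = key[a], src_minus = key[b], stringsAsFactors = FALSE)
      done[i] <- done[j] <- TRUE
    } else {
      cls <- if (segs$end[i] - segs$start[i] >= params$min_len) "eRNA" else "other"
      rows[[length(rows) + 1]] <- data.frame(
        chrom = segs$chrom[i], start = segs$start[i], end = segs$end[i],
        strand = segs$strand[i], class = cls,
        src_plus = if (segs$strand[i] == "+") key[i] else NA_character_,
        src_minus = if (segs$strand[i] == "-") key[i] else NA_character_,
        stringsAsFactors = FALSE)
      done[i] <- TRUE
    }
  }
  units <- do.call(rbind, rows)
  units <- units[order(match(units$chrom, names(chrom_lengths)), units$start,
                       units$end, units$strand), , drop = FALSE]
  pre <- ifelse(units$class == "genic", "txn", units$class)
  pre[pre == "eRNA"] <- "eRNA"
  units$id <- sprintf("%s.%s:%d-%d%s", pre, units$chrom, units$start, units$end,
                      ifelse(units$class == "genic", paste0(".", units$strand), ""))
  rownames(units) <- NULL
  units[c("id", "chrom", "start", "end", "strand", "class", "src_plus", "src_minus")]
}

#' Annotate eRNAs from a coverage set
#'
#' Pools coverage across samples, segments each strand, and classifies the
#' segments into genic / eRNA / other units.
#'
#' @param cs A [coverage_set()].
#' @param annotation A [build_genome()] annotation.
#' @param params A [segment_params()]; `tau = NULL` resolves against the
#'   pooled track count.
#' @param samples Samples to pool (default all).
#' @return Units data.frame (see [classify_units()]) with the resolved
#'   threshold in attribute `tau`.
#' @export
annotate_ernas <- function(cs, annotation, params = segment_params(),
                           samples = NULL) {
  pooled <- pool_coverage(cs, samples)
  tau <- resolve_tau(params, pooled)
  p2 <- params
  p2$tau <- tau
  segs <- lapply(c("+", "-"), function(st) {
    per_chrom <- lapply(names(cs$chrom_lengths), function(ch) {
      df <- segment_coverage(pooled[[st]][[ch]], p2, cs$bin_size)
      if (nrow(df)) cbind(chrom = ch, df, stringsAsFactors = FALSE) else NULL
    })
    do.call(rbind, per_chrom)
  })
  names(segs) <- c("+", "-")
  units <- classify_units(segs, annotation, p2)
  attr(units, "tau") <- tau
  units
}

#' Quantify units against per-sample coverage
#'
#' Sums per-bin coverage over each unit's span for every sample: genic units
#' are counted on their own strand, eRNA and other units over both strands.
#'
#' @param units Units data.frame from [classify_units()] /
#'   [annotate_ernas()], or any data.frame with `id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `class`.
#' @param cs A [coverage_set()].
#' @return A list of class `unit_counts`: integer matrix `counts`
#'   (units x samples), `units`, and the sample sheet.
#' @export
quantify_units <- function(units, cs) {
  stopifnot(inherits(cs, "coverage_set"))
  bad <- setdiff(unique(units$chrom), names(cs$chrom_lengths))
  if (length(bad)) {
    stopf("quantification error: unit chromosome(s) absent from tracks: %s",
          paste(bad, collapse = ", "))
  }
  if (any(units$end <= units$start)) stopf("quantification error: zero-length unit")
  bs <- cs$bin_size
  b0 <- floor(units$start / bs) + 1
  b1 <- ceiling(units$end / bs)
  k <- matrix(0L, nrow(units), nrow(cs$samples),
              dimnames = list(units$id, cs$samples$sample))
  for (s in cs$samples$sample) {
    for (i in seq_len(nrow(units))) {
      ch <- units$chrom[i]
      idx <- b0[i]:min(b1[i], length(cs$values[[s]][["+"]][[ch]]))
      tot <- if (units$class[i] == "genic") {
        sum(cs$values[[s]][[units$strand[i]]][[ch]][idx])
      } else {
        sum(cs$values[[s]][["+"]][[ch]][idx]) +
          sum(cs$values[[s]][["-"]][[ch]][idx])
      }
      k[i, s] <- as.integer(round(tot))
    }
  }
  structure(list(counts = k, units = units, samples = cs$samples),
            class = "unit_counts")
}

#' Convert quantified units of one class to a count matrix
#'
#' @param uc A [quantify_units()] result.
#' @param class Unit class to keep (`"eRNA"` or `"genic"`).
#' @return A [count_matrix()] (`feature_kind` `"eRNA"` or `"gene"`).
#' @export
as_count_matrix <- function(uc, class = "eRNA") {
  stopifnot(inherits(uc, "unit_counts"))
  keep <- uc$units$class == class
  if (!any(keep)) stopf("as_count_matrix: no units of class '%s'", class)
  count_matrix(uc$counts[keep, , drop = FALSE], uc$samples,
               if (class == "genic") "gene" else "eRNA")
}

#' Match annotated eRNA units against a planted truth set
#'
#' A detected eRNA matches a truth interval when their Jaccard overlap is at
#' least `min_jaccard`; each truth interval matches at most one unit.
#'
#' @param units Units data.frame (only `class == "eRNA"` rows are used).
#' @param truth data.frame with `chrom`, `start`, `end` (1-based closed, as
#'   in the transcription truth table).
#' @param min_jaccard Minimum intersection/union ratio.
#' @return List with `precision`, `recall`, `n_detected`, `n_truth`, and the
#'   matched index pairs.
#' @export
evaluate_erna_recovery <- function(units, truth, min_jaccard = 0.5) {
  det <- units[units$class == "eRNA", , drop = FALSE]
  if (!nrow(det) || !nrow(truth)) {
    return(list(precision = 0, recall = 0, n_detected = nrow(det),
                n_truth = nrow(truth), matches = NULL))
  }
  gd <- GenomicRanges::GRanges(det$chrom, IRanges::IRanges(det$start + 1, det$end))
  gt <- GenomicRanges::GRanges(truth$chrom, IRanges::IRanges(truth$start, truth$end))
  hits <- GenomicRanges::findOverlaps(gd, gt)
  if (!length(hits)) {
    return(list(precision = 0, recall = 0, n_detected = nrow(det),
                n_truth = nrow(truth), matches = NULL))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  inter <- GenomicRanges::width(GenomicRanges::pintersect(gd[qi], gt[si]))
  uni <- GenomicRanges::width(gd[qi]) + GenomicRanges::width(gt[si]) - inter
  jac <- inter / uni
  ok <- jac >= min_jaccard
  m <- unique(data.frame(det = qi[ok], truth = si[ok]))
  list(precision = length(unique(m$det)) / nrow(det),
       recall = length(unique(m$truth)) / nrow(truth),
       n_detected = nrow(det), n_truth = nrow(truth), matches = m)
}
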