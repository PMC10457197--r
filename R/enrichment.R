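# Genomic-context annotation of probes and exact enrichment statistics.

#' Annotate probes with genomic feature and CpG-context classes
#'
#' Each probe gets exactly one feature class, resolved by the priority
#' promoter > enhancer > gene_body > intergenic, and one CpG-context class
#' from its distance d (bp) to the nearest CpG island edge: island (d = 0),
#' shore (0 < d <= 2000), shelf (2000 < d <= 4000), open sea (d > 4000);
#' boundary values are assigned to the nearer-island class (inclusive upper
#' bounds).
#'
#' @param probes A width-1 `GRanges` with a `probe` id column, or `NULL` to
#'   use `annotation$probes`.
#' @param annotation A [build_genome()] annotation (or any list with
#'   `promoters`, `enhancers`, `genes`, `cpg_islands` GRanges).
#' @return A data.frame with columns `probe`, `feature_class`, `cpg_class`
#'   and `dist_to_island` (0 iff inside an island; `Inf` when the chromosome
#'   carries no island).
#' @export
annotate_probes <- function(probes = NULL, annotation) {
  probes <- probes %||% annotation$probes
  stopifnot(methods::is(probes, "GRanges"))
  known <- names(annotation$chrom_lengths) %||%
    GenomeInfoDb::seqlevels(annotation$genes)
  bad <- setdiff(as.character(GenomicRanges::seqnames(probes)), known)
  if (length(bad)) {
    stopf("annotation error: probes on unknown chromosome(s): %s",
          paste(unique(bad), collapse = ", "))
  }
  n <- length(probes)
  feature <- rep("intergenic", n)
  feature[IRanges::overlapsAny(probes, annotation$genes, ignore.strand = TRUE)] <- "gene_body"
  feature[IRanges::overlapsAny(probes, annotation$enhancers, ignore.strand = TRUE)] <- "enhancer"
  feature[IRanges::overlapsAny(probes, annotation$promoters, ignore.strand = TRUE)] <- "promoter"

  dist <- rep(Inf, n)
  hits <- GenomicRanges::distanceToNearest(probes, annotation$cpg_islands,
                                           ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  # GRanges distance counts bases strictly between ranges; edge-to-edge bp
  # distance is that plus one for disjoint ranges, 0 for overlaps.
  d0 <- S4Vectors::mcols(hits)$distance
  dist[qh] <- ifelse(d0 == 0 &
                       IRanges::overlapsAny(probes, annotation$cpg_islands,
                                            ignore.strand = TRUE)[qh],
                     0, d0 + 1)
  inside <- IRanges::overlapsAny(probes, annotation$cpg_islands, ignore.strand = TRUE)
  dist[inside] <- 0
  cpg <- cut(dist, c(-1, 0, 2000, 4000, Inf),
             labels = c("island", "shore", "shelf", "open_sea"))
  data.frame(probe = probes$probe,
             feature_class = feature,
             cpg_class = as.character(cpg),
             dist_to_island = dist,
             stringsAsFactors = FALSE)
}

#' Fisher exact enrichment of a selection across classes
#'
#' For every class, tests whether the selected ids are enriched (one-sided
#' greater) or depleted (one-sided less) relative to the universe, using the
#' exact hypergeometric tail, i.e. a one-sided Fisher exact test on the 2x2
#' table (selected-in-class, selected-out, unselected-in, unselected-out).
#' Works identically for probe feature classes, CpG-context classes, and gene
#' sets.
#'
#' @param selected Ids of the selection; must be a subset of `universe`.
#' @param universe All ids forming the background.
#' @param classes Either a named vector mapping every universe id to a class
#'   label, or an unnamed vector aligned with `universe`.
#' @return A data.frame with one row per class: 2x2 counts, odds ratio,
#'   `p_greater`, `p_less`, and BH-adjusted p within each direction across
#'   classes. An empty selection returns p = 1 everywhere with attribute
#'   `empty_selection = TRUE`.
#' @export
fisher_enrichment <- function(selected, universe, classes) {
  if (!length(universe)) stopf("fisher_enrichment: empty universe")
  if (anyDuplicated(universe)) stopf("fisher_enrichment: duplicated universe ids")
  if (is.null(names(classes))) {
    if (length(classes) != length(universe)) {
      stopf("fisher_enrichment: unnamed 'classes' must align with 'universe'")
    }
    names(classes) <- universe
  }
  if (!all(universe %in% names(classes))) {
    stopf("fisher_enrichment: classes missing for some universe ids")
  }
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stopf("fisher_enrichment: %d selected ids not in universe (e.g. %s)",
          length(extra), paste(utils::head(extra, 3), collapse = ", "))
  }
  cl <- as.character(classes[universe])
  sel <- universe %in% selected
  N <- length(universe)
  n_sel <- sum(sel)
  labs <- sort(unique(cl))
  rows <- lapply(labs, function(lb) {
    K <- sum(cl == lb)
    a <- sum(sel & cl == lb)
    b <- n_sel - a
    c_ <- K - a
    d_ <- N - K - b
    pp <- fisher_one_sided(a, n_sel, K, N)
    data.frame(class = lb, selected_in = a, selected_out = b,
               unselected_in = c_, unselected_out = d_,
               odds_ratio = (a * d_) / (b * c_),
               p_greater = pp$p_greater, p_less = pp$p_less,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj_greater <- bh_adjust(out$p_greater)
  out$p_adj_less <- bh_adjust(out$p_less)
  if (n_sel == 0) {
    out$p_greater <- out$p_adj_greater <- 1
    out$p_less <- out$p_adj_less <- 1
    attr(out, "empty_selection") <- TRUE
  }
  out
}
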