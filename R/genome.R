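# Synthetic genome annotation: chromosomes, gene bodies, strand-aware
# promoters, enhancers, CpG islands, array-style probes and named gene sets.
# A stand-in for hg38/EPIC-array geometry at desk scale, with full control of
# placement so downstream truth tables are exact.

#' Specification of a synthetic genome
#'
#' Defaults describe the package's desk-scale genome: ~20,000 probes over
#' 1,000 genes and 300 enhancers on three 10 Mb chromosomes, mirroring the
#' probe-context mix of a methylation array (island / shore / shelf / open-sea
#' coverage plus promoter, gene-body, enhancer and intergenic probes), and one
#' contiguous 12-gene cluster standing in for the HLA locus.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Total number of non-overlapping gene bodies.
#' @param gene_length_range Min/max gene length (bp).
#' @param n_enhancers Number of enhancers, each placed at least
#'   `min_feature_gap` bp from any gene and from each other.
#' @param enhancer_length_range Min/max enhancer length (bp).
#' @param n_cpg_islands Number of CpG islands, placed independently of genes.
#' @param island_length_range Min/max island length (bp).
#' @param probes_per_island_region Probes placed per island region: inside the
#'   island and at graded shore (<=2 kb), shelf (2-4 kb) and open-sea (>4 kb)
#'   distances.
#' @param probes_per_promoter,probes_per_gene_body,probes_per_enhancer Probes
#'   placed uniformly inside each feature of the class.
#' @param intergenic_probe_count Probes placed outside genes, promoters and
#'   enhancers.
#' @param cluster_n_genes Number of contiguous genes forming the `HLA_like`
#'   gene set.
#' @param probes_per_cluster_gene Extra probes placed in each cluster gene
#'   (half promoter, half gene body) so the cluster carries a dense probe set.
#' @param min_feature_gap Minimum gap (bp) between placed features.
#' @param seed Integer seed; identical specs give byte-identical genomes.
#' @return A validated object of class `genome_spec`.
#' @export
genome_spec <- function(n_chroms = 3L,
                        chrom_length = 1e7,
                        n_genes = 1000L,
                        gene_length_range = c(2000, 8000),
                        n_enhancers = 300L,
                        enhancer_length_range = c(400, 1200),
                        n_cpg_islands = 600L,
                        island_length_range = c(500, 2000),
                        probes_per_island_region = 16L,
                        probes_per_promoter = 2L,
                        probes_per_gene_body = 2L,
                        probes_per_enhancer = 5L,
                        intergenic_probe_count = 4000L,
                        cluster_n_genes = 12L,
                        probes_per_cluster_gene = 6L,
                        min_feature_gap = 3000,
                        seed = 1L) {
  spec <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes), gene_length_range = as.numeric(gene_length_range),
    n_enhancers = as.integer(n_enhancers),
    enhancer_length_range = as.numeric(enhancer_length_range),
    n_cpg_islands = as.integer(n_cpg_islands),
    island_length_range = as.numeric(island_length_range),
    probes_per_island_region = as.integer(probes_per_island_region),
    probes_per_promoter = as.integer(probes_per_promoter),
    probes_per_gene_body = as.integer(probes_per_gene_body),
    probes_per_enhancer = as.integer(probes_per_enhancer),
    intergenic_probe_count = as.integer(intergenic_probe_count),
    cluster_n_genes = as.integer(cluster_n_genes),
    probes_per_cluster_gene = as.integer(probes_per_cluster_gene),
    min_feature_gap = as.numeric(min_feature_gap), seed = as.integer(seed)
  )
  counts <- c("n_chroms", "n_genes", "n_enhancers", "n_cpg_islands",
              "probes_per_island_region", "probes_per_promoter",
              "probes_per_gene_body", "probes_per_enhancer",
              "cluster_n_genes", "probes_per_cluster_gene")
  for (f in counts) if (spec[[f]] <= 0L) stopf("genome_spec: '%s' must be > 0", f)
  if (spec$intergenic_probe_count < 0L) stopf("genome_spec: 'intergenic_probe_count' must be >= 0")
  if (spec$min_feature_gap < 0) stopf("genome_spec: 'min_feature_gap' must be >= 0")
  if (spec$chrom_length <= 0) stopf("genome_spec: 'chrom_length' must be > 0")
  for (f in c("gene_length_range", "enhancer_length_range", "island_length_range")) {
    r <- spec[[f]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      stopf("genome_spec: '%s' must be an increasing positive pair", f)
    }
    if (r[2] > spec$chrom_length) stopf("genome_spec: '%s' exceeds chromosome length", f)
  }
  if (spec$cluster_n_genes > spec$n_genes) {
    stopf("genome_spec: cluster_n_genes exceeds n_genes")
  }
  structure(spec, class = "genome_spec")
}

# Free-space allocator. `free` is a data.frame(chrom, start, end) of 1-based
# closed intervals still available. Placing a feature removes the feature
# interval plus `margin` bp on each side. Errors name the feature class
# (explicit placement error, with a pigeonhole pre-check).
alloc_features <- function(free, lens, margin, label) {
  avail <- sum(free$end - free$start + 1)
  if (avail < sum(lens) + length(lens) * margin) {
    stopf("placement error: cannot place %d %s features (%d bp required incl. %d bp gaps, %d bp available)",
          length(lens), label, round(sum(lens) + length(lens) * margin),
          round(margin), round(avail))
  }
  out <- data.frame(chrom = character(length(lens)), start = numeric(length(lens)),
                    end = numeric(length(lens)), stringsAsFactors = FALSE)
  for (i in seq_along(lens)) {
    len <- lens[i]
    w <- free$end - free$start + 1
    ok <- which(w >= len)
    if (!length(ok)) {
      stopf("placement error: no remaining space for %s feature %d of %d",
            label, i, length(lens))
    }
    seg <- if (length(ok) == 1) ok else sample(ok, 1, prob = w[ok] - len + 1)
    off <- if (w[seg] == len) 0 else sample.int(w[seg] - len + 1, 1) - 1
    s <- free$start[seg] + off
    e <- s + len - 1
    out$chrom[i] <- free$chrom[seg]
    out$start[i] <- s
    out$end[i] <- e
    left <- data.frame(chrom = free$chrom[seg], start = free$start[seg],
                       end = s - margin - 1, stringsAsFactors = FALSE)
    right <- data.frame(chrom = free$chrom[seg], start = e + margin + 1,
                        end = free$end[seg], stringsAsFactors = FALSE)
    free <- rbind(free[-seg, , drop = FALSE],
                  left[left$end >= left$start, , drop = FALSE],
                  right[right$end >= right$start, , drop = FALSE])
  }
  list(placed = out, free = free)
}

df_to_gr <- function(df, chrom_lengths, ids = NULL, id_col = "id",
                     strand = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand %||% "*",
    seqlengths = chrom_lengths
  )
  if (!is.null(ids)) S4Vectors::mcols(gr)[[id_col]] <- ids
  gr
}

# Promoter: TSS -1000/+500 bp, half-open, strand-aware (1-based closed here).
promoters_from_genes <- function(genes_df, chrom_lengths, up = 1000, down = 500) {
  plus <- genes_df$strand == "+"
  start <- ifelse(plus, genes_df$start - up, genes_df$end - down + 1)
  end <- ifelse(plus, genes_df$start + down - 1, genes_df$end + up)
  data.frame(chrom = genes_df$chrom,
             start = pmax(1, start),
             end = pmin(chrom_lengths[genes_df$chrom], end),
             strand = genes_df$strand,
             stringsAsFactors = FALSE)
}

#' Build a synthetic genome annotation
#'
#' Places non-overlapping gene bodies, derives strand-aware promoters
#' (TSS -1000/+500 bp), places enhancers at least `min_feature_gap` bp from
#' genes, places CpG islands independently with wide spacing so graded probe
#' distances are unambiguous, and lays down probes inside islands, at shore /
#' shelf / open-sea distances, in promoters, gene bodies, enhancers and
#' intergenic space. A contiguous run of genes on the first chromosome forms
#' the named gene set `HLA_like` and carries a dense probe set.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `genome_annotation`: GRanges for `genes`,
#'   `promoters`, `enhancers`, `cpg_islands` and `probes` (width-1), plus
#'   `gene_sets` (named list of gene ids), `cluster_probes` (probe ids lying
#'   in cluster genes or their promoters) and `chrom_lengths`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, build_genome_impl(spec))
}

build_genome_impl <- function(spec) {
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  chrom_lengths <- stats::setNames(rep(spec$chrom_length, spec$n_chroms), chroms)
  free0 <- data.frame(chrom = chroms, start = 1, end = spec$chrom_length,
                      stringsAsFactors = FALSE)

  # Genes, then enhancers in the remaining gene-free space.
  gene_lens <- round(stats::runif(spec$n_genes, spec$gene_length_range[1],
                                  spec$gene_length_range[2]))
  g <- alloc_features(free0, gene_lens, spec$min_feature_gap, "gene")
  genes <- g$placed
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  enh_lens <- round(stats::runif(spec$n_enhancers, spec$enhancer_length_range[1],
                                 spec$enhancer_length_range[2]))
  e <- alloc_features(g$free, enh_lens, spec$min_feature_gap, "enhancer")
  enhancers <- e$placed

  # CpG islands: independent of genes; spacing wide enough (>= 16 kb) that a
  # probe planted within 8 kb of one island is always nearest to that island.
  island_margin <- max(spec$min_feature_gap, 16001)
  isl_lens <- round(stats::runif(spec$n_cpg_islands, spec$island_length_range[1],
                                 spec$island_length_range[2]))
  isl <- alloc_features(free0, isl_lens, island_margin, "cpg_island")
  islands <- isl$placed

  # Coordinate-sorted ids.
  ord <- function(df) order(match(df$chrom, chroms), df$start)
  genes <- genes[ord(genes), , drop = FALSE]
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  enhancers <- enhancers[ord(enhancers), , drop = FALSE]
  enhancers$enhancer_id <- sprintf("enh%04d", seq_len(nrow(enhancers)))
  islands <- islands[ord(islands), , drop = FALSE]
  islands$island_id <- sprintf("cgi%04d", seq_len(nrow(islands)))

  promoters <- promoters_from_genes(genes, chrom_lengths)
  promoters$gene_id <- genes$gene_id

  # HLA-like cluster: a contiguous run of genes on chr1.
  chr1_idx <- which(genes$chrom == chroms[1])
  if (length(chr1_idx) < spec$cluster_n_genes) {
    stopf("placement error: fewer than %d genes on %s for the HLA_like cluster",
          spec$cluster_n_genes, chroms[1])
  }
  k <- sample.int(length(chr1_idx) - spec$cluster_n_genes + 1L, 1)
  cluster_genes <- genes$gene_id[chr1_idx[k:(k + spec$cluster_n_genes - 1L)]]

  # Probes ------------------------------------------------------------------
  unif_in <- function(df, per) {
    idx <- rep(seq_len(nrow(df)), each = per)
    data.frame(chrom = df$chrom[idx],
               pos = round(stats::runif(length(idx), df$start[idx], df$end[idx])),
               stringsAsFactors = FALSE)
  }
  # Island regions: inside + graded distances for shore/shelf/open-sea cover.
  n_in <- max(1L, round(spec$probes_per_island_region * 6 / 16))
  n_shore <- max(1L, round(spec$probes_per_island_region * 4 / 16))
  n_shelf <- max(1L, round(spec$probes_per_island_region * 3 / 16))
  n_open <- max(0L, spec$probes_per_island_region - n_in - n_shore - n_shelf)
  graded <- function(lo, hi, per) {
    if (per == 0L) return(NULL)
    idx <- rep(seq_len(nrow(islands)), each = per)
    d <- round(stats::runif(length(idx), lo, hi))
    side <- sample(c(-1, 1), length(idx), replace = TRUE)
    pos <- ifelse(side < 0, islands$start[idx] - d, islands$end[idx] + d)
    bad <- pos < 1 | pos > chrom_lengths[islands$chrom[idx]]
    pos[bad] <- ifelse(side[bad] < 0, islands$end[idx][bad] + d[bad],
                       islands$start[idx][bad] - d[bad])
    data.frame(chrom = islands$chrom[idx], pos = pos, stringsAsFactors = FALSE)
  }
  probes <- rbind(
    unif_in(islands, n_in),
    graded(1, 2000, n_shore),
    graded(2001, 4000, n_shelf),
    graded(4001, 8000, n_open),
    unif_in(promoters, spec$probes_per_promoter),
    unif_in(genes, spec$probes_per_gene_body),
    unif_in(enhancers, spec$probes_per_enhancer)
  )
  # Dense probe set in the cluster genes (half promoter, half gene body).
  cl_genes <- genes[genes$gene_id %in% cluster_genes, , drop = FALSE]
  cl_prom <- promoters[promoters$gene_id %in% cluster_genes, , drop = FALSE]
  n_half <- ceiling(spec$probes_per_cluster_gene / 2)
  probes <- rbind(probes, unif_in(cl_prom, n_half),
                  unif_in(cl_genes, spec$probes_per_cluster_gene - n_half))
  # Intergenic probes: rejection-sample away from genes/promoters/enhancers.
  if (spec$intergenic_probe_count > 0L) {
    occupied <- GenomicRanges::reduce(c(
      df_to_gr(genes, chrom_lengths), df_to_gr(promoters, chrom_lengths),
      df_to_gr(enhancers, chrom_lengths)
    ))
    got <- NULL
    for (tries in 1:50) {
      need <- spec$intergenic_probe_count - NROW(got)
      if (need <= 0) break
      cand <- data.frame(
        chrom = sample(chroms, 2L * need, replace = TRUE),
        pos = NA_real_, stringsAsFactors = FALSE
      )
      cand$pos <- round(stats::runif(nrow(cand), 1, chrom_lengths[cand$chrom]))
      hit <- IRanges::overlapsAny(df_to_gr(data.frame(
        chrom = cand$chrom, start = cand$pos, end = cand$pos), chrom_lengths),
        occupied)
      got <- rbind(got, cand[!hit, , drop = FALSE])
    }
    if (NROW(got) < spec$intergenic_probe_count) {
      stopf("placement error: could not place %d intergenic probes",
            spec$intergenic_probe_count)
    }
    probes <- rbind(probes, got[seq_len(spec$intergenic_probe_count), , drop = FALSE])
  }
  probes$pos <- pmin(pmax(probes$pos, 1), chrom_lengths[probes$chrom])
  probes <- probes[order(match(probes$chrom, chroms), probes$pos), , drop = FALSE]
  probes <- probes[!duplicated(probes[c("chrom", "pos")]), , drop = FALSE]
  probes$probe <- sprintf("cg%06d", seq_len(nrow(probes)))

  ann <- structure(list(
    genes = df_to_gr(genes, chrom_lengths, genes$gene_id, "gene_id", genes$strand),
    promoters = df_to_gr(promoters, chrom_lengths, promoters$gene_id, "gene_id",
                         promoters$strand),
    enhancers = df_to_gr(enhancers, chrom_lengths, enhancers$enhancer_id,
                         "enhancer_id"),
    cpg_islands = df_to_gr(islands, chrom_lengths, islands$island_id, "island_id"),
    probes = df_to_gr(data.frame(chrom = probes$chrom, start = probes$pos,
                                 end = probes$pos), chrom_lengths,
                      probes$probe, "probe"),
    gene_sets = list(HLA_like = cluster_genes),
    chrom_lengths = chrom_lengths,
    spec = spec
  ), class = "genome_annotation")
  cl_gr <- c(GenomicRanges::granges(ann$genes[ann$genes$gene_id %in% cluster_genes]),
             GenomicRanges::granges(ann$promoters[ann$promoters$gene_id %in% cluster_genes]))
  ann$cluster_probes <- ann$probes$probe[IRanges::overlapsAny(ann$probes, cl_gr)]
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(paste0(
    "genome_annotation: %d chroms (%.1f Mb each), %d genes, %d enhancers,\n",
    "  %d CpG islands, %d probes; gene sets: %s\n"),
    length(x$chrom_lengths), x$chrom_lengths[1] / 1e6,
    length(x$genes), length(x$enhancers), length(x$cpg_islands),
    length(x$probes),
    paste(sprintf("%s (%d)", names(x$gene_sets), lengths(x$gene_sets)),
          collapse = ", ")))
  invisible(x)
}

# Strand-aware TSS positions (1-based) per gene.
gene_tss <- function(ann) {
  g <- ann$genes
  data.frame(
    gene = g$gene_id,
    chrom = as.character(GenomicRanges::seqnames(g)),
    tss = ifelse(as.character(GenomicRanges::strand(g)) == "+",
                 GenomicRanges::start(g), GenomicRanges::end(g)),
    strand = as.character(GenomicRanges::strand(g)),
    stringsAsFactors = FALSE
  )
}
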