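# Plain-text interchange: TSV tables, BED6 annotation, bedGraph coverage.
# All on-disk coordinates are 0-based half-open; in-memory GRanges are
# 1-based closed.

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

gr_to_bed <- function(gr, names) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = names,
             score = 0L,
             strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
             stringsAsFactors = FALSE)
}

write_bed <- function(gr, names, path) {
  data.table::fwrite(gr_to_bed(gr, names), path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}

read_bed <- function(path, chrom_lengths) {
  df <- as.data.frame(data.table::fread(
    path, sep = "\t", header = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand")))
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = sub("\\.", "*", df$strand),
                         name = df$name,
                         seqlengths = chrom_lengths)
}

#' Write a genome annotation to a directory
#'
#' BED6 per feature class (`genes.bed`, `promoters.bed`, `enhancers.bed`,
#' `cpg_islands.bed`), `probes.tsv` (probe, chrom, 0-based position),
#' `chroms.tsv`, and `gene_sets.tsv` (set, gene).
#'
#' @param ann A [build_genome()] annotation.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(ann$genes, ann$genes$gene_id, file.path(dir, "genes.bed"))
  write_bed(ann$promoters, ann$promoters$gene_id, file.path(dir, "promoters.bed"))
  write_bed(ann$enhancers, ann$enhancers$enhancer_id, file.path(dir, "enhancers.bed"))
  write_bed(ann$cpg_islands, ann$cpg_islands$island_id, file.path(dir, "cpg_islands.bed"))
  write_tsv(data.frame(probe = ann$probes$probe,
                       chrom = as.character(GenomicRanges::seqnames(ann$probes)),
                       pos = GenomicRanges::start(ann$probes) - 1L),
            file.path(dir, "probes.tsv"))
  write_tsv(data.frame(chrom = names(ann$chrom_lengths),
                       length = unname(ann$chrom_lengths)),
            file.path(dir, "chroms.tsv"))
  sets <- do.call(rbind, lapply(names(ann$gene_sets), function(s) {
    data.frame(set = s, gene = ann$gene_sets[[s]], stringsAsFactors = FALSE)
  }))
  write_tsv(sets, file.path(dir, "gene_sets.tsv"))
  invisible(dir)
}

#' Read a genome annotation written by [write_genome_annotation()]
#'
#' @param dir Directory holding the annotation files.
#' @return A `genome_annotation` (without the originating spec).
#' @export
read_genome_annotation <- function(dir) {
  ch <- read_tsv(file.path(dir, "chroms.tsv"))
  chrom_lengths <- stats::setNames(ch$length, ch$chrom)
  rn <- function(gr, col) {
    names(S4Vectors::mcols(gr)) <- col
    gr
  }
  ann <- structure(list(
    genes = rn(read_bed(file.path(dir, "genes.bed"), chrom_lengths), "gene_id"),
    promoters = rn(read_bed(file.path(dir, "promoters.bed"), chrom_lengths), "gene_id"),
    enhancers = rn(read_bed(file.path(dir, "enhancers.bed"), chrom_lengths), "enhancer_id"),
    cpg_islands = rn(read_bed(file.path(dir, "cpg_islands.bed"), chrom_lengths), "island_id"),
    chrom_lengths = chrom_lengths,
    spec = NULL
  ), class = "genome_annotation")
  pr <- read_tsv(file.path(dir, "probes.tsv"))
  ann$probes <- GenomicRanges::GRanges(pr$chrom,
                                       IRanges::IRanges(pr$pos + 1L, pr$pos + 1L),
                                       probe = pr$probe,
                                       seqlengths = chrom_lengths)
  sets <- read_tsv(file.path(dir, "gene_sets.tsv"))
  ann$gene_sets <- split(sets$gene, sets$set)
  cl <- ann$gene_sets$HLA_like
  cl_gr <- c(GenomicRanges::granges(ann$genes[ann$genes$gene_id %in% cl]),
             GenomicRanges::granges(ann$promoters[ann$promoters$gene_id %in% cl]))
  ann$cluster_probes <- ann$probes$probe[IRanges::overlapsAny(ann$probes, cl_gr)]
  ann
}

#' Write a beta matrix (values + sample sheet) to TSV
#'
#' @param bm A [beta_matrix()].
#' @param values_path,sheet_path Output paths; the sheet carries the assay.
#' @return `values_path`, invisibly.
#' @export
write_beta <- function(bm, values_path, sheet_path) {
  df <- data.frame(probe = rownames(bm$values), bm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, values_path)
  sheet <- bm$samples
  sheet$assay <- bm$assay
  write_tsv(sheet, sheet_path)
  invisible(values_path)
}

#' Read a beta matrix written by [write_beta()]
#'
#' @param values_path,sheet_path Input paths.
#' @return A [beta_matrix()].
#' @export
read_beta <- function(values_path, sheet_path) {
  df <- read_tsv(values_path)
  sheet <- read_tsv(sheet_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe
  beta_matrix(m, sheet[c("sample", "condition", "replicate")],
              assay = unique(sheet$assay))
}

#' Write a count matrix (counts + design) to TSV
#' @param cm A [count_matrix()].
#' @param counts_path,design_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(cm, counts_path, design_path) {
  df <- data.frame(feature = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  sheet <- cm$samples
  sheet$feature_kind <- cm$feature_kind
  write_tsv(sheet, design_path)
  invisible(counts_path)
}

#' Read a count matrix written by [write_counts()]
#' @param counts_path,design_path Input paths.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, design_path) {
  df <- read_tsv(counts_path)
  sheet <- read_tsv(design_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature
  count_matrix(m, sheet[c("sample", "condition", "replicate")],
               feature_kind = unique(sheet$feature_kind))
}

bedgraph_name <- function(sample, strand) {
  sprintf("%s.%s.bedGraph", sample, if (strand == "+") "plus" else "minus")
}

#' Write a coverage set as bedGraph files
#'
#' One file per sample and strand (`<sample>.plus.bedGraph` /
#' `<sample>.minus.bedGraph`), run-length encoded over bins, covering every
#' bin (zero runs included) with 0-based half-open coordinates.
#'
#' @param cs A [coverage_set()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_coverage <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bs <- cs$bin_size
  for (s in cs$samples$sample) {
    for (st in c("+", "-")) {
      parts <- lapply(names(cs$chrom_lengths), function(ch) {
        v <- cs$values[[s]][[st]][[ch]]
        r <- rle(v)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        data.table::data.table(chrom = ch, start = (starts - 1) * bs,
                               end = pmin(ends * bs, cs$chrom_lengths[[ch]]),
                               value = r$values)
      })
      data.table::fwrite(data.table::rbindlist(parts),
                         file.path(dir, bedgraph_name(s, st)),
                         sep = "\t", col.names = FALSE)
    }
  }
  write_tsv(cbind(cs$samples, bin_size = bs), file.path(dir, "coverage_samples.tsv"))
  invisible(dir)
}

#' Read a coverage set written by [write_coverage()]
#'
#' @param dir Directory with bedGraph files and `coverage_samples.tsv`.
#' @param chrom_lengths Named chromosome lengths.
#' @return A [coverage_set()].
#' @export
read_coverage <- function(dir, chrom_lengths) {
  sheet <- read_tsv(file.path(dir, "coverage_samples.tsv"))
  bs <- unique(sheet$bin_size)
  nbins <- ceiling(chrom_lengths / bs)
  values <- lapply(stats::setNames(nm = sheet$sample), function(s) {
    tr <- lapply(c("+", "-"), function(st) {
      df <- data.table::fread(file.path(dir, bedgraph_name(s, st)),
                              sep = "\t", header = FALSE,
                              col.names = c("chrom", "start", "end", "value"))
      lapply(stats::setNames(nm = names(chrom_lengths)), function(ch) {
        d <- df[df$chrom == ch, ]
        v <- rep(d$value, ceiling(d$end / bs) - floor(d$start / bs))
        if (length(v) != nbins[[ch]]) {
          stopf("read_coverage: %s/%s/%s has %d bins, expected %d",
                s, st, ch, length(v), nbins[[ch]])
        }
        v
      })
    })
    names(tr) <- c("+", "-")
    tr
  })
  coverage_set(values, bs, chrom_lengths,
               sheet[c("sample", "condition", "replicate")])
}

#' Write transcription units as BED6
#'
#' The name field carries `<id>|<class>`.
#'
#' @param units Units data.frame from [classify_units()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_units_bed <- function(units, path) {
  df <- data.frame(chrom = units$chrom, start = units$start, end = units$end,
                   name = paste(units$id, units$class, sep = "|"),
                   score = 0L, strand = sub("\\*", ".", units$strand),
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcription units written by [write_units_bed()]
#' @param path BED path.
#' @return Units data.frame (`id`, `chrom`, `start`, `end`, `strand`,
#'   `class`).
#' @export
read_units_bed <- function(path) {
  df <- as.data.frame(data.table::fread(
    path, sep = "\t", header = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand")))
  parts <- strsplit(df$name, "|", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, character(1), 1),
             chrom = df$chrom, start = df$start, end = df$end,
             strand = sub("\\.", "*", df$strand),
             class = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}
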