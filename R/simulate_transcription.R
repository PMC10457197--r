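# Nascent-transcription simulator: strand-specific coverage tracks built from
# planted transcription units (genes on their own strand, eRNAs on one or
# both strands) plus Poisson background, and NB count matrices implementing
# the planted condition log2 fold changes.

condition_multipliers <- function(eff, lfc, is_hla = FALSE) {
  if (is_hla) {
    # HLA-like genes are repressed in the mutant and NOT restored by treatment.
    c(1, 2^lfc, 2^lfc, 2^lfc)
  } else {
    c(1, 2^lfc,
      2^(lfc * (1 - eff$reversal_fraction_t4)),
      2^(lfc * (1 - eff$reversal_fraction_t7)))
  }
}

#' Simulate nascent-transcription coverage and counts with planted effects
#'
#' Every gene is transcribed on its own strand at a per-bin rate; a subset of
#' enhancers transcribe eRNAs (bidirectional units cover both strands,
#' single-strand units one random strand). Planted differential genes and
#' eRNAs scale their rate by `2^lfc` in the mutant, relaxing back by the
#' reversal fractions at the treated time points; HLA-like cluster genes are
#' repressed and not restored. Coverage is per-bin Poisson around the
#' condition rate plus Poisson background; count matrices (genes, eRNAs) are
#' drawn NB with condition-specific means, emulating equal sequencing depth
#' up to size factors. Planted enhancer-promoter pairs put a de-regulated
#' enhancer within 500 kb of a concordantly de-regulated gene.
#'
#' @param annotation A [build_genome()] annotation.
#' @param effects An [effect_config()].
#' @return A list: `coverage` ([coverage_set()]), `counts_genes`,
#'   `counts_ernas` ([count_matrix()] objects), and `truth` (gene/eRNA truth
#'   tables, planted sets, E-P pairs).
#' @export
simulate_transcription <- function(annotation, effects) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(effects, "effect_config"))
  seed <- derive_seeds(effects$seed)[["transcription"]]
  with_seed(seed, simulate_transcription_impl(annotation, effects))
}

simulate_transcription_impl <- function(ann, eff) {
  conds <- eff$conditions
  design <- make_design(conds, eff$replicates_per_condition)
  genes <- data.frame(
    gene = ann$genes$gene_id,
    chrom = as.character(GenomicRanges::seqnames(ann$genes)),
    start = GenomicRanges::start(ann$genes),
    end = GenomicRanges::end(ann$genes),
    strand = as.character(GenomicRanges::strand(ann$genes)),
    stringsAsFactors = FALSE
  )
  enh <- data.frame(
    enhancer = ann$enhancers$enhancer_id,
    chrom = as.character(GenomicRanges::seqnames(ann$enhancers)),
    start = GenomicRanges::start(ann$enhancers),
    end = GenomicRanges::end(ann$enhancers),
    stringsAsFactors = FALSE
  )
  hla_genes <- ann$gene_sets$HLA_like

  # Expressed eRNAs and their differential subset.
  if (eff$n_expressed_ernas > nrow(enh)) {
    stopf("simulate_transcription: n_expressed_ernas exceeds enhancers")
  }
  expressed <- sort(sample(enh$enhancer, eff$n_expressed_ernas))
  bidir <- sort(sample(expressed, eff$n_bidirectional_ernas))
  n_de_e <- eff$n_ernas_up + eff$n_ernas_down
  if (n_de_e > length(expressed)) {
    stopf("simulate_transcription: more differential eRNAs than expressed")
  }
  de_e <- sample(expressed, n_de_e)
  ernas_up <- sort(de_e[seq_len(eff$n_ernas_up)])
  ernas_down <- sort(de_e[eff$n_ernas_up + seq_len(eff$n_ernas_down)])
  erna_lfc <- stats::setNames(rep(0, length(expressed)), expressed)
  erna_lfc[ernas_up] <- eff$erna_lfc
  erna_lfc[ernas_down] <- -eff$erna_lfc

  # Planted E-P pairs: de-regulated enhancer within 500 kb of a concordantly
  # de-regulated gene; then fill the remaining gene quotas.
  tssd <- gene_tss(ann)
  emid <- midpoint0(enh$start - 1, enh$end)
  names(emid) <- enh$enhancer
  gene_dir <- stats::setNames(rep("none", nrow(genes)), genes$gene)
  ep <- list()
  cand_e <- sample(c(ernas_up, ernas_down))
  quota <- c(up = eff$n_genes_up, down = eff$n_genes_down)
  for (e in cand_e) {
    if (length(ep) >= eff$n_ep_pairs) break
    dir <- if (e %in% ernas_up) "up" else "down"
    if (quota[[dir]] <= 0) next
    i <- match(e, enh$enhancer)
    cand_g <- tssd[tssd$chrom == enh$chrom[i] &
                     abs(tssd$tss - emid[[e]]) <= 5e5 &
                     !(tssd$gene %in% hla_genes) &
                     gene_dir[tssd$gene] == "none", , drop = FALSE]
    if (!nrow(cand_g)) next
    g <- cand_g$gene[sample.int(nrow(cand_g), 1)]
    gene_dir[g] <- dir
    quota[[dir]] <- quota[[dir]] - 1L
    ep[[length(ep) + 1]] <- data.frame(
      enhancer = e, gene = g,
      chrom = enh$chrom[i], start = enh$start[i], end = enh$end[i],
      distance = tssd$tss[tssd$gene == g] - 1 - emid[[e]],
      direction = dir, stringsAsFactors = FALSE)
  }
  if (length(ep) < eff$n_ep_pairs) {
    stopf("simulate_transcription: could only place %d of %d E-P pairs",
          length(ep), eff$n_ep_pairs)
  }
  ep <- if (length(ep)) do.call(rbind, ep) else
    data.frame(enhancer = character(0), gene = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               distance = numeric(0), direction = character(0))
  pool <- setdiff(genes$gene, c(hla_genes, names(gene_dir)[gene_dir != "none"]))
  extra <- sample(pool, quota[["up"]] + quota[["down"]])
  if (quota[["up"]] > 0) gene_dir[extra[seq_len(quota[["up"]])]] <- "up"
  if (quota[["down"]] > 0) gene_dir[extra[quota[["up"]] + seq_len(quota[["down"]])]] <- "down"
  gene_lfc <- stats::setNames(rep(0, nrow(genes)), genes$gene)
  gene_lfc[gene_dir == "up"] <- eff$gene_lfc
  gene_lfc[gene_dir == "down"] <- -eff$gene_lfc
  gene_lfc[hla_genes] <- eff$hla_log2fc

  # Condition mean multipliers.
  mult_gene <- t(vapply(genes$gene, function(g) {
    condition_multipliers(eff, gene_lfc[[g]], g %in% hla_genes)
  }, numeric(4)))
  colnames(mult_gene) <- conds
  mult_erna <- t(vapply(expressed, function(e) {
    condition_multipliers(eff, erna_lfc[[e]], FALSE)
  }, numeric(4)))
  colnames(mult_erna) <- conds

  # NB count matrices (equal depth up to size factors).
  draw_counts <- function(ids, mult) {
    mu0 <- exp(stats::runif(length(ids), log(eff$mean_count_range[1]),
                            log(eff$mean_count_range[2])))
    k <- sapply(seq_len(nrow(design)), function(j) {
      m <- mu0 * mult[, design$condition[j]]
      if (eff$nb_dispersion <= 0) stats::rpois(length(ids), m)
      else stats::rnbinom(length(ids), mu = m, size = 1 / eff$nb_dispersion)
    })
    dimnames(k) <- list(ids, design$sample)
    list(k = k, mu0 = mu0)
  }
  gcounts <- draw_counts(genes$gene, mult_gene)
  ecounts <- draw_counts(expressed, mult_erna)

  # Coverage tracks: Poisson background + rectangular unit blocks.
  bs <- eff$bin_size
  nbins <- stats::setNames(as.integer(ceiling(ann$chrom_lengths / bs)),
                           names(ann$chrom_lengths))
  gene_rate <- stats::setNames(
    stats::runif(nrow(genes), eff$gene_rate_range[1], eff$gene_rate_range[2]),
    genes$gene)
  erna_rate <- stats::setNames(
    stats::runif(length(expressed), eff$erna_rate_range[1], eff$erna_rate_range[2]),
    expressed)
  erna_strand <- stats::setNames(
    sample(c("+", "-"), length(expressed), replace = TRUE), expressed)
  erna_strand[bidir] <- "*"

  bin_span <- function(start, end) (floor((start - 1) / bs) + 1):ceiling(end / bs)
  gene_bins <- lapply(seq_len(nrow(genes)), function(i) bin_span(genes$start[i], genes$end[i]))
  ei <- match(expressed, enh$enhancer)
  erna_bins <- lapply(ei, function(i) bin_span(enh$start[i], enh$end[i]))

  values <- lapply(stats::setNames(nm = design$sample), function(s) {
    cc <- design$condition[match(s, design$sample)]
    tr <- lapply(c("+", "-"), function(st) {
      lapply(stats::setNames(nm = names(nbins)), function(ch) {
        if (eff$background_rate > 0) stats::rpois(nbins[[ch]], eff$background_rate)
        else integer(nbins[[ch]])
      })
    })
    names(tr) <- c("+", "-")
    for (i in seq_len(nrow(genes))) {
      st <- genes$strand[i]
      ch <- genes$chrom[i]
      rate <- gene_rate[[genes$gene[i]]] * mult_gene[i, cc]
      b <- gene_bins[[i]]
      tr[[st]][[ch]][b] <- tr[[st]][[ch]][b] + stats::rpois(length(b), rate)
    }
    for (j in seq_along(expressed)) {
      ch <- enh$chrom[ei[j]]
      b <- erna_bins[[j]]
      rate <- erna_rate[[expressed[j]]] * mult_erna[j, cc]
      sts <- if (erna_strand[[expressed[j]]] == "*") c("+", "-") else erna_strand[[expressed[j]]]
      for (st in sts) {
        tr[[st]][[ch]][b] <- tr[[st]][[ch]][b] + stats::rpois(length(b), rate)
      }
    }
    tr
  })
  cs <- coverage_set(values, bs, ann$chrom_lengths, design)

  erna_truth <- data.frame(
    enhancer = expressed,
    chrom = enh$chrom[ei], start = enh$start[ei], end = enh$end[ei],
    strand = unname(erna_strand[expressed]),
    bidirectional = expressed %in% bidir,
    rate = unname(erna_rate[expressed]),
    lfc = unname(erna_lfc[expressed]),
    base_mean = unname(ecounts$mu0),
    stringsAsFactors = FALSE
  )
  gene_truth <- cbind(genes,
                      data.frame(lfc = unname(gene_lfc[genes$gene]),
                                 is_hla = genes$gene %in% hla_genes,
                                 rate = unname(gene_rate[genes$gene]),
                                 base_mean = unname(gcounts$mu0)))
  list(
    coverage = cs,
    counts_genes = count_matrix(gcounts$k, design, "gene"),
    counts_ernas = count_matrix(ecounts$k, design, "eRNA"),
    truth = list(
      genes = gene_truth, ernas = erna_truth, ep_pairs = ep,
      sets = list(genes_up = sort(names(gene_dir)[gene_dir == "up"]),
                  genes_down = sort(names(gene_dir)[gene_dir == "down"]),
                  ernas_up = ernas_up, ernas_down = ernas_down,
                  hla_genes = hla_genes, expressed_ernas = expressed)
    )
  )
}
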