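# Shared small-scale fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

small_spec <- function(seed = 7) {
  genome_spec(n_chroms = 1, chrom_length = 3e6, n_genes = 80,
              n_enhancers = 40, n_cpg_islands = 50,
              intergenic_probe_count = 400, cluster_n_genes = 6,
              probes_per_cluster_gene = 6, seed = seed)
}

small_effects <- function(seed = 3, ...) {
  effect_config(n_hyper_5mc = 150, n_hypo_5mc = 70, n_loss_5hmc = 100,
                n_gain_5hmc = 40, n_genes_up = 8, n_genes_down = 10,
                n_ernas_up = 8, n_ernas_down = 5, n_ep_pairs = 5,
                n_expressed_ernas = 30, n_bidirectional_ernas = 8,
                seed = seed, ...)
}

small_annotation <- function() {
  if (is.null(.fixtures$ann)) .fixtures$ann <- build_genome(small_spec())
  .fixtures$ann
}

small_methylome <- function() {
  if (is.null(.fixtures$meth)) {
    .fixtures$meth <- simulate_methylome(small_annotation(), small_effects())
  }
  .fixtures$meth
}

small_transcription <- function() {
  if (is.null(.fixtures$txn)) {
    .fixtures$txn <- simulate_transcription(small_annotation(), small_effects())
  }
  .fixtures$txn
}

# A hand-built annotation on one 100 kb chromosome for exact-coordinate tests.
toy_annotation <- function() {
  cl <- c(chrT = 1e5)
  gr <- function(s, e, strand = "*", ids = NULL, col = "id") {
    g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(s, e),
                                strand = strand, seqlengths = cl)
    if (!is.null(ids)) S4Vectors::mcols(g)[[col]] <- ids
    g
  }
  structure(list(
    genes = gr(c(10001, 40001), c(15000, 44000), c("+", "-"),
               c("gA", "gB"), "gene_id"),
    promoters = gr(c(9001, 43501), c(10500, 45000), c("+", "-"),
                   c("gA", "gB"), "gene_id"),
    enhancers = gr(20001, 20800, "*", "eX", "enhancer_id"),
    cpg_islands = gr(c(50001, 80001), c(51000, 80600), "*",
                     c("cgi1", "cgi2"), "island_id"),
    gene_sets = list(HLA_like = "gA"),
    chrom_lengths = cl,
    spec = NULL
  ), class = "genome_annotation")
}

toy_probes <- function(pos) {
  GenomicRanges::GRanges("chrT", IRanges::IRanges(pos, pos),
                         probe = sprintf("p%03d", seq_along(pos)),
                         seqlengths = c(chrT = 1e5))
}

# Beta matrices straight from value matrices (2 conditions).
toy_beta_pair <- function(bs_vals, oxbs_vals, conditions = c("A", "A", "B", "B")) {
  design <- data.frame(sample = colnames(bs_vals), condition = conditions,
                       replicate = c(1, 2, 1, 2))
  list(bs = beta_matrix(bs_vals, design, "BS"),
       oxbs = beta_matrix(oxbs_vals, design, "oxBS"))
}
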