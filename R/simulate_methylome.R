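# Planted-effect configuration and the paired BS/oxBS methylome simulator.
# The generator writes the study's effect structure into truth tables first
# (per-probe true 5mC/5hmC per condition), then observes it through
# truncated-normal array noise, so every downstream estimator can be scored
# against exact truth.

#' Planted-effect configuration
#'
#' Defaults encode the study conditions the package emulates: a duplicate
#' design over four conditions (wild-type, IDH2-mutant, and mutant after 4 and
#' 7 days of inhibitor treatment); a hypermethylation skew of ~2.15:1
#' (3000 hyper vs 1400 hypo 5mC sites, the published genome-wide skew scaled
#' to the desk-scale probe count); 2156 5hmC-loss vs 664 5hmC-gain sites (the
#' published ~3:1 loss:gain counts, used as-is); anti-correlated construction
#' (5hmC loss compensated by 5mC gain at the same site); partial reversal of
#' planted effects after treatment (80% at day 4, 90% at day 7); and one
#' HLA-like cluster that is hypermethylated, transcriptionally down-regulated,
#' and *not* reversed by treatment (the non-responder retention pattern).
#'
#' @param conditions Four ordered condition labels: reference, mutant, and two
#'   treated time points.
#' @param replicates_per_condition Replicates per condition (biological
#'   duplicates by default).
#' @param n_hyper_5mc,n_hypo_5mc Planted pure 5mC hyper-/hypomethylated sites.
#' @param n_loss_5hmc,n_gain_5hmc Planted 5hmC loss/gain sites (each with a
#'   compensating opposite 5mC change).
#' @param delta_effect Planted |delta-beta| magnitude.
#' @param reversal_fraction_t4,reversal_fraction_t7 Fraction of each planted
#'   effect reversed at the two treated time points (HLA-like probes excepted).
#' @param n_genes_up,n_genes_down,n_ernas_up,n_ernas_down Planted
#'   differentially expressed genes/eRNAs (mutant vs reference).
#' @param gene_lfc,erna_lfc Planted |log2 fold change| for genes and eRNAs.
#' @param n_ep_pairs Planted co-regulated enhancer-promoter pairs (a
#'   de-regulated enhancer within 500 kb of a concordantly de-regulated gene).
#' @param hla_n_probes Number of HLA-like cluster probes carrying retained
#'   hypermethylation; `NULL` (default) plants the effect on every probe in
#'   the cluster (~120 at the default genome, the scale of the published
#'   116-site HLA class I retention set), so the cluster is uniformly
#'   hypermethylated.
#' @param hla_log2fc Log2 fold change of HLA-like cluster genes in the mutant.
#' @param hla_delta_beta Hypermethylation delta-beta of HLA-like probes.
#' @param beta_noise_sd SD of observed beta around truth (truncated to
#'   \[0, 1\]).
#' @param nb_dispersion Negative-binomial dispersion of simulated counts
#'   (0.01: tight cell-line biological duplicates).
#' @param mean_count_range Range of baseline feature mean counts (drawn
#'   log-uniformly).
#' @param n_expressed_ernas Enhancers that transcribe an eRNA (200 of 300 by
#'   default), of which `n_bidirectional_ernas` are divergent two-strand units.
#' @param n_bidirectional_ernas Bidirectional (divergent) eRNA units.
#' @param gene_rate_range,erna_rate_range Per-sample coverage rates
#'   (reads/bin) for transcribed genes and eRNA strands.
#' @param background_rate Poisson background coverage rate (reads/bin/sample).
#' @param bin_size Coverage bin size (bp).
#' @param seed Integer seed expanded into per-stage substreams (order:
#'   genome, methylome, transcription, motifs, gsea).
#' @return A validated object of class `effect_config`.
#' @export
effect_config <- function(conditions = c("WT", "MUT", "MUT_T4", "MUT_T7"),
                          replicates_per_condition = 2L,
                          n_hyper_5mc = 3000L,
                          n_hypo_5mc = 1400L,
                          n_loss_5hmc = 2156L,
                          n_gain_5hmc = 664L,
                          delta_effect = 0.2,
                          reversal_fraction_t4 = 0.8,
                          reversal_fraction_t7 = 0.9,
                          n_genes_up = 40L,
                          n_genes_down = 60L,
                          n_ernas_up = 30L,
                          n_ernas_down = 20L,
                          gene_lfc = 1.5,
                          erna_lfc = 1.5,
                          n_ep_pairs = 20L,
                          hla_n_probes = NULL,
                          hla_log2fc = -2,
                          hla_delta_beta = 0.2,
                          beta_noise_sd = 0.03,
                          nb_dispersion = 0.01,
                          mean_count_range = c(50, 500),
                          n_expressed_ernas = 200L,
                          n_bidirectional_ernas = 50L,
                          gene_rate_range = c(1.5, 6),
                          erna_rate_range = c(3, 6),
                          background_rate = 0.1,
                          bin_size = 10L,
                          seed = 1L) {
  eff <- list(
    conditions = as.character(conditions),
    replicates_per_condition = as.integer(replicates_per_condition),
    n_hyper_5mc = as.integer(n_hyper_5mc), n_hypo_5mc = as.integer(n_hypo_5mc),
    n_loss_5hmc = as.integer(n_loss_5hmc), n_gain_5hmc = as.integer(n_gain_5hmc),
    delta_effect = as.numeric(delta_effect),
    reversal_fraction_t4 = as.numeric(reversal_fraction_t4),
    reversal_fraction_t7 = as.numeric(reversal_fraction_t7),
    n_genes_up = as.integer(n_genes_up), n_genes_down = as.integer(n_genes_down),
    n_ernas_up = as.integer(n_ernas_up), n_ernas_down = as.integer(n_ernas_down),
    gene_lfc = as.numeric(gene_lfc), erna_lfc = as.numeric(erna_lfc),
    n_ep_pairs = as.integer(n_ep_pairs),
    hla_n_probes = if (is.null(hla_n_probes)) NULL else as.integer(hla_n_probes),
    hla_log2fc = as.numeric(hla_log2fc),
    hla_delta_beta = as.numeric(hla_delta_beta),
    beta_noise_sd = as.numeric(beta_noise_sd),
    nb_dispersion = as.numeric(nb_dispersion),
    mean_count_range = as.numeric(mean_count_range),
    n_expressed_ernas = as.integer(n_expressed_ernas),
    n_bidirectional_ernas = as.integer(n_bidirectional_ernas),
    gene_rate_range = as.numeric(gene_rate_range),
    erna_rate_range = as.numeric(erna_rate_range),
    background_rate = as.numeric(background_rate),
    bin_size = as.integer(bin_size),
    seed = as.integer(seed)
  )
  if (length(eff$conditions) != 4L || anyDuplicated(eff$conditions)) {
    stopf("effect_config: 'conditions' must be four distinct ordered labels")
  }
  if (eff$replicates_per_condition < 1L) {
    stopf("effect_config: 'replicates_per_condition' must be >= 1")
  }
  for (f in c("n_hyper_5mc", "n_hypo_5mc", "n_loss_5hmc", "n_gain_5hmc",
              "n_genes_up", "n_genes_down", "n_ernas_up", "n_ernas_down",
              "n_ep_pairs")) {
    if (eff[[f]] < 0L) stopf("effect_config: '%s' must be >= 0", f)
  }
  if (!is.null(eff$hla_n_probes) && eff$hla_n_probes < 0L) {
    stopf("effect_config: 'hla_n_probes' must be >= 0")
  }
  for (f in c("reversal_fraction_t4", "reversal_fraction_t7")) {
    if (eff[[f]] < 0 || eff[[f]] > 1) stopf("effect_config: '%s' must be in [0, 1]", f)
  }
  if (eff$delta_effect < 0 || eff$delta_effect > 1) {
    stopf("effect_config: 'delta_effect' must be in [0, 1]")
  }
  if (eff$beta_noise_sd < 0) stopf("effect_config: 'beta_noise_sd' must be >= 0")
  if (eff$nb_dispersion < 0) stopf("effect_config: 'nb_dispersion' must be >= 0")
  if (eff$background_rate < 0) stopf("effect_config: 'background_rate' must be >= 0")
  if (eff$n_bidirectional_ernas > eff$n_expressed_ernas) {
    stopf("effect_config: more bidirectional than expressed eRNAs")
  }
  if (eff$n_ep_pairs > min(eff$n_ernas_up + eff$n_ernas_down,
                           eff$n_genes_up + eff$n_genes_down)) {
    stopf("effect_config: n_ep_pairs exceeds available differential eRNAs or genes")
  }
  structure(eff, class = "effect_config")
}

# Context weights used when planting differential 5mC/5hmC sites: changed
# sites land in enhancers at 3x the relative rate, are depleted from
# promoters and CpG islands, and favour open sea, mirroring the observed
# genomic distribution of 5hmC change.
PLANT_FEATURE_WEIGHTS <- c(promoter = 1 / 3, enhancer = 3, gene_body = 1.5,
                           intergenic = 1)
PLANT_CPG_WEIGHTS <- c(island = 1 / 3, shore = 1 / 2, shelf = 1, open_sea = 1.5)

#' Simulate a paired BS/oxBS methylome with planted effects
#'
#' True per-probe (5mC, 5hmC) states are built per condition: 5hmC-loss sites
#' lose `delta_effect` of 5hmC in the mutant with a compensating 5mC gain
#' (and vice versa for gain sites), pure 5mC sites shift by `delta_effect`,
#' and HLA-like cluster probes are hypermethylated. At the treated time points
#' every planted effect relaxes back toward the reference state by the
#' configured reversal fraction -- except the HLA-like probes, which retain
#' their mutant methylation. Observed betas are truth plus zero-mean
#' truncated-normal noise; the BS assay reads 5mC + 5hmC and the oxBS assay
#' 5mC only.
#'
#' @param annotation A [build_genome()] annotation.
#' @param effects An [effect_config()].
#' @return A list with `bs` and `oxbs` [beta_matrix()] objects and `truth`
#'   (true `m`/`h` probe x condition matrices, planted-set membership lists,
#'   and the number of truth values clamped into \[0, 1\]).
#' @export
simulate_methylome <- function(annotation, effects) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(effects, "effect_config"))
  seed <- derive_seeds(effects$seed)[["methylome"]]
  with_seed(seed, simulate_methylome_impl(annotation, effects))
}

simulate_methylome_impl <- function(ann, eff) {
  probes <- ann$probes$probe
  n <- length(probes)
  conds <- eff$conditions
  ctx <- annotate_probes(ann$probes, ann)
  w <- PLANT_FEATURE_WEIGHTS[ctx$feature_class] * PLANT_CPG_WEIGHTS[ctx$cpg_class]

  hla <- if (is.null(eff$hla_n_probes)) {
    sort(ann$cluster_probes)
  } else {
    if (eff$hla_n_probes > length(ann$cluster_probes)) {
      stopf("effect counts exceed eligible probes: %d HLA-like probes requested, %d available in the cluster",
            eff$hla_n_probes, length(ann$cluster_probes))
    }
    sort(sample(ann$cluster_probes, eff$hla_n_probes))
  }
  eligible <- setdiff(probes, ann$cluster_probes)
  n_tot <- eff$n_loss_5hmc + eff$n_gain_5hmc + eff$n_hyper_5mc + eff$n_hypo_5mc
  if (n_tot > length(eligible)) {
    stopf("effect counts exceed eligible probes: %d planted, %d eligible",
          n_tot, length(eligible))
  }
  idx <- match(eligible, probes)
  picked <- sample(eligible, n_tot, prob = w[idx])
  sets <- list(
    loss_5hmc = sort(picked[seq_len(eff$n_loss_5hmc)]),
    gain_5hmc = sort(picked[eff$n_loss_5hmc + seq_len(eff$n_gain_5hmc)]),
    hyper_5mc = sort(picked[eff$n_loss_5hmc + eff$n_gain_5hmc +
                              seq_len(eff$n_hyper_5mc)]),
    hypo_5mc = sort(picked[eff$n_loss_5hmc + eff$n_gain_5hmc + eff$n_hyper_5mc +
                             seq_len(eff$n_hypo_5mc)]),
    hla = hla
  )
  cls <- rep("none", n)
  for (s in names(sets)) cls[probes %in% sets[[s]]] <- s

  # Baseline (reference) state: bimodal 5mC, low 5hmC, with planted probes
  # pulled into ranges that keep all condition states inside [0, 1].
  d <- eff$delta_effect
  u <- stats::runif(n)
  m0 <- ifelse(u < 0.35, stats::rbeta(n, 2, 10),
               ifelse(u < 0.80, stats::rbeta(n, 10, 2), stats::rbeta(n, 2, 2)))
  h0 <- pmin(stats::rbeta(n, 2, 18), pmax(1 - m0 - 0.01, 0))
  ov <- function(set, lo, hi) stats::runif(length(set), lo, hi)
  i <- cls == "loss_5hmc"
  h0[i] <- ov(which(i), d + 0.05, min(d + 0.2, 0.45))
  m0[i] <- ov(which(i), 0.15, 0.5)
  i <- cls == "gain_5hmc"
  h0[i] <- ov(which(i), 0.02, 0.08)
  m0[i] <- ov(which(i), d + 0.1, min(d + 0.5, 0.7))
  i <- cls %in% c("hyper_5mc", "hla")
  h0[i] <- ov(which(i), 0, 0.08)
  m0[i] <- ov(which(i), 0.15, 0.6)
  i <- cls == "hypo_5mc"
  h0[i] <- ov(which(i), 0, 0.08)
  m0[i] <- ov(which(i), d + 0.1, 0.85)

  m <- matrix(m0, n, 4, dimnames = list(probes, conds))
  h <- matrix(h0, n, 4, dimnames = list(probes, conds))
  mut <- conds[2]
  shift <- function(mat, set, delta) {
    mat[probes %in% set, mut] <- mat[probes %in% set, mut] + delta
    mat
  }
  h <- shift(h, sets$loss_5hmc, -d); m <- shift(m, sets$loss_5hmc, +d)
  h <- shift(h, sets$gain_5hmc, +d); m <- shift(m, sets$gain_5hmc, -d)
  m <- shift(m, sets$hyper_5mc, +d)
  m <- shift(m, sets$hypo_5mc, -d)
  m <- shift(m, sets$hla, eff$hla_delta_beta)

  # Treated time points: planted effects relax toward the reference by the
  # reversal fraction; HLA-like probes retain the mutant state.
  keep <- probes %in% sets$hla
  for (tc in c(3, 4)) {
    f <- if (tc == 3) eff$reversal_fraction_t4 else eff$reversal_fraction_t7
    m[, conds[tc]] <- m[, mut] + f * (m[, conds[1]] - m[, mut])
    h[, conds[tc]] <- h[, mut] + f * (h[, conds[1]] - h[, mut])
    m[keep, conds[tc]] <- m[keep, mut]
    h[keep, conds[tc]] <- h[keep, mut]
  }

  # Conservation guard: clamp truth into m >= 0, h >= 0, m + h <= 1.
  n_clamped <- sum(m < 0 | m > 1 | h < 0 | h > 1 | m + h > 1)
  m <- pmin(pmax(m, 0), 1)
  h <- pmin(pmax(h, 0), 1 - m)
  if (n_clamped > 0) {
    warnf("simulate_methylome: %d truth values clamped into [0, 1]", n_clamped)
  }

  design <- make_design(conds, eff$replicates_per_condition)
  observe <- function(truth) {
    vals <- truth[, design$condition, drop = FALSE]
    colnames(vals) <- design$sample
    if (eff$beta_noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(length(vals), 0, eff$beta_noise_sd),
                            nrow(vals), ncol(vals))
      vals <- pmin(pmax(vals, 0), 1)
    }
    vals
  }
  bs <- beta_matrix(observe(m + h), design, "BS")
  oxbs <- beta_matrix(observe(m), design, "oxBS")
  list(bs = bs, oxbs = oxbs,
       truth = list(m = m, h = h, sets = sets, probe_class = cls,
                    n_clamped = n_clamped))
}
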