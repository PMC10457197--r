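# Pipeline configuration, stage runners and end-to-end orchestration.
# Every stage reads its inputs from the output directory written by earlier
# stages and writes plain-text TSV/BED/bedGraph outputs, so each stage can be
# re-run in isolation and two runs with the same config are byte-identical.

#' Default pipeline configuration
#'
#' Nested list of every stage parameter with its default: the simulated
#' genome and planted effects, the 0.05 delta-beta calling threshold, the
#' segmentation parameters, DE significance levels (0.05 for genes, 0.1 for
#' eRNAs), the 500 kb enhancer-promoter window, the 0.05 retention
#' threshold, and the motif-stage synthetic-sequence settings.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    genome = list(),      # overrides for genome_spec()
    effects = list(),     # overrides for effect_config()
    methylome = list(delta_threshold = 0.05, test = "none", alpha = NULL),
    segmentation = list(tau = NULL, gap = 200, min_len = 200,
                        d_ex = 1000, d_pair = 1000),
    de = list(alpha_genes = 0.05, alpha_ernas = 0.1,
              alpha_min = 1e-8, shrink = 0.5),
    integration = list(window = 5e5, require_concordant = TRUE,
                       retention_threshold = 0.05, gsea_n_perm = 1000),
    motifs = list(n_targets = 100, n_background = 500, seq_width = 300,
                  plant_fraction_targets = 0.9,
                  plant_fraction_background = 0.05,
                  n_decoys = 10, score_fraction = 0.8)
  )
}

merge_config <- function(base, user, path = "", errors) {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown key: %s", full))
      next
    }
    if (is.null(user[[k]])) next # explicit null keeps the default
    if (is.list(base[[k]]) && !is.null(user[[k]]) && !is.list(user[[k]]) &&
        length(base[[k]]) > 0) {
      errors$msgs <- c(errors$msgs, sprintf("key %s must be a mapping", full))
      next
    }
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !k %in% c("genome", "effects")) {
      base[[k]] <- merge_config(base[[k]], user[[k]], full, errors)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

check_range <- function(cfg, errors) {
  chk <- function(val, key, lo = -Inf, hi = Inf, null_ok = FALSE) {
    if (is.null(val)) {
      if (!null_ok) errors$msgs <- c(errors$msgs, sprintf("missing value: %s", key))
      return()
    }
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) ||
        val < lo || val > hi) {
      errors$msgs <- c(errors$msgs,
                       sprintf("out-of-range value for %s: %s (allowed [%s, %s])",
                               key, paste(val, collapse = ","), lo, hi))
    }
  }
  chk(cfg$seed, "seed", 0, .Machine$integer.max)
  chk(cfg$methylome$delta_threshold, "methylome.delta_threshold", 0, 1)
  if (!is.null(cfg$methylome$test) &&
      !cfg$methylome$test %in% c("none", "welch_t")) {
    errors$msgs <- c(errors$msgs, "methylome.test must be 'none' or 'welch_t'")
  }
  chk(cfg$methylome$alpha, "methylome.alpha", 0, 1, null_ok = TRUE)
  if (!is.null(cfg$segmentation$tau) && !identical(cfg$segmentation$tau, "q90")) {
    chk(cfg$segmentation$tau, "segmentation.tau", 1e-9)
  }
  chk(cfg$segmentation$gap, "segmentation.gap", 0)
  chk(cfg$segmentation$min_len, "segmentation.min_len", 0)
  chk(cfg$segmentation$d_ex, "segmentation.d_ex", 0)
  chk(cfg$segmentation$d_pair, "segmentation.d_pair", 0)
  chk(cfg$de$alpha_genes, "de.alpha_genes", 0, 1)
  chk(cfg$de$alpha_ernas, "de.alpha_ernas", 0, 1)
  chk(cfg$de$alpha_min, "de.alpha_min", 0)
  chk(cfg$de$shrink, "de.shrink", 0, 1)
  chk(cfg$integration$window, "integration.window", 0)
  chk(cfg$integration$retention_threshold, "integration.retention_threshold", 0, 1)
  chk(cfg$integration$gsea_n_perm, "integration.gsea_n_perm", 1)
  if (!is.logical(cfg$integration$require_concordant)) {
    errors$msgs <- c(errors$msgs, "integration.require_concordant must be logical")
  }
  chk(cfg$motifs$n_targets, "motifs.n_targets", 1)
  chk(cfg$motifs$n_background, "motifs.n_background", 1)
  chk(cfg$motifs$seq_width, "motifs.seq_width", 20)
  chk(cfg$motifs$plant_fraction_targets, "motifs.plant_fraction_targets", 0, 1)
  chk(cfg$motifs$plant_fraction_background, "motifs.plant_fraction_background", 0, 1)
  chk(cfg$motifs$n_decoys, "motifs.n_decoys", 0)
  chk(cfg$motifs$score_fraction, "motifs.score_fraction", 1e-9, 1)
  invisible(NULL)
}

#' Validate and resolve a pipeline configuration
#'
#' Accepts a nested list, a YAML file path, or YAML text; merges it over
#' [default_config()], rejects unknown keys, range-checks every value, and
#' resolves the genome spec and effect config. All violations are reported
#' together in one error.
#'
#' @param x Configuration (list, YAML path, YAML text) or `NULL` for pure
#'   defaults.
#' @return An object of class `pipeline_config` with elements `raw` (the
#'   merged plain list), `seed`, `seeds` (per-stage substreams),
#'   `genome_spec`, `effects`, and the stage parameter groups.
#' @export
validate_config <- function(x = NULL) {
  user <- if (is.null(x)) {
    list()
  } else if (is.list(x)) {
    x
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    yaml::read_yaml(x) %||% list()
  } else if (is.character(x)) {
    yaml::yaml.load(paste(x, collapse = "\n")) %||% list()
  } else {
    stopf("validate_config: unsupported config input")
  }
  errors <- new.env()
  errors$msgs <- character(0)
  cfg <- merge_config(default_config(), user, "", errors)
  check_range(cfg, errors)
  seeds <- NULL
  spec <- NULL
  eff <- NULL
  if (!length(errors$msgs)) {
    seeds <- derive_seeds(cfg$seed)
    spec <- tryCatch(
      do.call(genome_spec, c(cfg$genome, list(seed = seeds[["genome"]]))),
      error = function(e) {
        errors$msgs <<- c(errors$msgs, paste0("genome: ", conditionMessage(e)))
        NULL
      })
    eff <- tryCatch(
      do.call(effect_config, c(cfg$effects, list(seed = cfg$seed))),
      error = function(e) {
        errors$msgs <<- c(errors$msgs, paste0("effects: ", conditionMessage(e)))
        NULL
      })
  }
  if (length(errors$msgs)) {
    stopf("invalid configuration:\n  - %s", paste(errors$msgs, collapse = "\n  - "))
  }
  structure(c(list(raw = cfg, seed = as.integer(cfg$seed), seeds = seeds,
                   genome_spec = spec, effects = eff),
              cfg[c("methylome", "segmentation", "de", "integration", "motifs")]),
            class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param config A `pipeline_config` (or plain list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- if (inherits(config, "pipeline_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

stage_dir <- function(out_dir, stage) {
  d <- file.path(out_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

#' Simulation stage: genome, methylome, transcription, truth tables
#'
#' @param config A [validate_config()] result.
#' @param out_dir Pipeline output directory.
#' @return The output directory, invisibly.
#' @export
stage_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  ann <- build_genome(config$genome_spec)
  write_genome_annotation(ann, stage_dir(out_dir, "annotation"))

  sim <- simulate_methylome(ann, config$effects)
  d <- stage_dir(out_dir, "methylome")
  write_beta(sim$bs, file.path(d, "bs.tsv"), file.path(d, "bs_samples.tsv"))
  write_beta(sim$oxbs, file.path(d, "oxbs.tsv"), file.path(d, "oxbs_samples.tsv"))
  tm <- data.frame(probe = rownames(sim$truth$m), sim$truth$m, check.names = FALSE)
  th <- data.frame(probe = rownames(sim$truth$h), sim$truth$h, check.names = FALSE)
  write_tsv(tm, file.path(d, "truth_m.tsv"))
  write_tsv(th, file.path(d, "truth_h.tsv"))
  sets <- do.call(rbind, lapply(names(sim$truth$sets), function(s) {
    if (!length(sim$truth$sets[[s]])) return(NULL)
    data.frame(set = s, probe = sim$truth$sets[[s]], stringsAsFactors = FALSE)
  }))
  if (is.null(sets)) sets <- data.frame(set = character(0), probe = character(0))
  write_tsv(sets, file.path(d, "truth_sets.tsv"))

  txn <- simulate_transcription(ann, config$effects)
  d <- stage_dir(out_dir, "txn")
  write_coverage(txn$coverage, file.path(d, "coverage"))
  write_counts(txn$counts_genes, file.path(d, "counts_genes.tsv"),
               file.path(d, "counts_genes_design.tsv"))
  write_counts(txn$counts_ernas, file.path(d, "counts_ernas.tsv"),
               file.path(d, "counts_ernas_design.tsv"))
  write_tsv(txn$truth$genes, file.path(d, "truth_genes.tsv"))
  write_tsv(txn$truth$ernas, file.path(d, "truth_ernas.tsv"))
  write_tsv(txn$truth$ep_pairs, file.path(d, "truth_ep_pairs.tsv"))
  invisible(out_dir)
}

read_pipeline_betas <- function(out_dir) {
  d <- file.path(out_dir, "methylome")
  list(bs = read_beta(file.path(d, "bs.tsv"), file.path(d, "bs_samples.tsv")),
       oxbs = read_beta(file.path(d, "oxbs.tsv"), file.path(d, "oxbs_samples.tsv")))
}

#' Methylome stage: 5hmC estimation, delta-beta contrasts, calls, z-scores
#'
#' Contrasts: mutant vs reference, and each treated time point vs mutant.
#' Calls use the configured |delta-beta| threshold (and `alpha` when a test
#' is configured); the anti-correlation between 5hmC and 5mC changes is
#' computed over the called 5hmC-differential probes of each contrast.
#'
#' @inheritParams stage_simulate
#' @return The output directory, invisibly.
#' @export
stage_methylome <- function(config, out_dir) {
  b <- read_pipeline_betas(out_dir)
  est <- estimate_5hmc(b$bs, b$oxbs)
  conds <- config$effects$conditions
  contrasts <- list(mut = c(conds[1], conds[2]),
                    t4 = c(conds[2], conds[3]),
                    t7 = c(conds[2], conds[4]))
  d <- stage_dir(out_dir, "delta")
  cors <- list()
  deltas <- list()
  for (nm in names(contrasts)) {
    tab <- delta_beta(est, contrasts[[nm]], test = config$methylome$test)
    tab <- call_differential(tab, config$methylome$delta_threshold,
                             config$methylome$alpha)
    write_tsv(as.data.frame(tab), file.path(d, sprintf("delta_%s.tsv", nm)))
    sel <- tab$probe[tab$mark == "h" & tab$call != "none"]
    cors[[nm]] <- if (length(sel) >= 3) {
      r <- correlate_changes(tab, probes = sel)
      data.frame(contrast = nm, r = r$r, n = r$n)
    } else {
      data.frame(contrast = nm, r = NA_real_, n = length(sel))
    }
    deltas[[nm]] <- tab
  }
  write_tsv(do.call(rbind, cors), file.path(d, "correlations.tsv"))

  # z-score profiles of 5hmC delta-beta across contrasts (loss-site heatmap
  # analogue): rows standardized over the three contrasts.
  hmat <- sapply(deltas, function(tab) {
    hh <- tab[tab$mark == "h", ]
    stats::setNames(hh$delta, hh$probe)
  })
  z <- standardize_profiles(hmat)
  write_tsv(data.frame(probe = rownames(z$z), z$z, constant = z$constant,
                       check.names = FALSE),
            file.path(d, "zscores.tsv"))
  invisible(out_dir)
}

#' Enrichment stage: probe contexts and Fisher enrichment of changed sites
#'
#' @inheritParams stage_simulate
#' @return The output directory, invisibly.
#' @export
stage_enrich <- function(config, out_dir) {
  ann <- read_genome_annotation(file.path(out_dir, "annotation"))
  ctx <- annotate_probes(ann$probes, ann)
  d <- stage_dir(out_dir, "enrichment")
  write_tsv(ctx, file.path(d, "probe_context.tsv"))
  tab <- read_tsv(file.path(out_dir, "delta", "delta_mut.tsv"))
  sel <- tab$probe[tab$mark == "h" & tab$call != "none"]
  write_tsv(fisher_enrichment(sel, ctx$probe,
                              stats::setNames(ctx$feature_class, ctx$probe)),
            file.path(d, "enrichment_feature.tsv"))
  write_tsv(fisher_enrichment(sel, ctx$probe,
                              stats::setNames(ctx$cpg_class, ctx$probe)),
            file.path(d, "enrichment_cpg.tsv"))
  invisible(out_dir)
}

#' eRNA stage: pooled segmentation, classification, quantification
#'
#' @inheritParams stage_simulate
#' @return The output directory, invisibly.
#' @export
stage_ernas <- function(config, out_dir) {
  ann <- read_genome_annotation(file.path(out_dir, "annotation"))
  cs <- read_coverage(file.path(out_dir, "txn", "coverage"), ann$chrom_lengths)
  params <- do.call(segment_params, config$segmentation)
  units <- annotate_ernas(cs, ann, params)
  d <- stage_dir(out_dir, "ernas")
  write_units_bed(units, file.path(d, "units.bed"))
  writeLines(sprintf("tau\t%g", attr(units, "tau")), file.path(d, "tau.tsv"))
  uc <- quantify_units(units[units$class == "eRNA", , drop = FALSE], cs)
  write_counts(as_count_matrix(uc, "eRNA"),
               file.path(d, "erna_counts.tsv"),
               file.path(d, "erna_counts_design.tsv"))
  invisible(out_dir)
}

#' Differential-expression stage: genes (three contrasts) and annotated eRNAs
#'
#' @inheritParams stage_simulate
#' @return The output directory, invisibly.
#' @export
stage_de <- function(config, out_dir) {
  conds <- config$effects$conditions
  d <- stage_dir(out_dir, "de")
  genes <- read_counts(file.path(out_dir, "txn", "counts_genes.tsv"),
                       file.path(out_dir, "txn", "counts_genes_design.tsv"))
  for (ct in list(c("mut", 1, 2), c("t4", 2, 3), c("t7", 2, 4))) {
    res <- nb_wald(genes, c(conds[as.integer(ct[2])], conds[as.integer(ct[3])]),
                   alpha = config$de$alpha_genes,
                   alpha_min = config$de$alpha_min, shrink = config$de$shrink)
    write_tsv(as.data.frame(res), file.path(d, sprintf("de_genes_%s.tsv", ct[1])))
  }
  ernas <- read_counts(file.path(out_dir, "ernas", "erna_counts.tsv"),
                       file.path(out_dir, "ernas", "erna_counts_design.tsv"))
  res <- nb_wald(ernas, c(conds[1], conds[2]), alpha = config$de$alpha_ernas,
                 alpha_min = config$de$alpha_min, shrink = config$de$shrink)
  write_tsv(as.data.frame(res), file.path(d, "de_ernas_mut.tsv"))
  invisible(out_dir)
}

#' Integration stage: E-P pairs, reversal overlap, GSEA, retention
#'
#' @inheritParams stage_simulate
#' @return The output directory, invisibly.
#' @export
stage_integrate <- function(config, out_dir) {
  ann <- read_genome_annotation(file.path(out_dir, "annotation"))
  d <- stage_dir(out_dir, "integration")
  de_g <- read_tsv(file.path(out_dir, "de", "de_genes_mut.tsv"))
  de_g7 <- read_tsv(file.path(out_dir, "de", "de_genes_t7.tsv"))
  de_e <- read_tsv(file.path(out_dir, "de", "de_ernas_mut.tsv"))
  units <- read_units_bed(file.path(out_dir, "ernas", "units.bed"))
  tss <- gene_tss(ann)

  links <- pair_enhancer_promoter(de_e, units, de_g, tss,
                                  window = config$integration$window,
                                  require_concordant = config$integration$require_concordant)
  write_tsv(links, file.path(d, "ep_pairs.tsv"))

  # Reversal overlap: genes down in the mutant that come back up under
  # treatment, hypergeometric against all tested genes.
  down_mut <- de_g$feature[de_g$direction == "down"]
  up_t7 <- de_g7$feature[de_g7$direction == "up"]
  ov <- overlap_test(down_mut, up_t7, de_g$feature)
  write_tsv(data.frame(n_down_mut = ov$n_a, n_up_t7 = ov$n_b,
                       overlap = ov$overlap, universe = ov$universe, p = ov$p),
            file.path(d, "reversal_overlap.tsv"))

  # Preranked GSEA of the HLA-like set on the mutant-vs-reference ranking.
  scores <- stats::setNames(de_g$stat, de_g$feature)
  gs <- preranked_gsea(scores, ann$gene_sets$HLA_like,
                       n_perm = config$integration$gsea_n_perm,
                       seed = config$seeds[["gsea"]])
  write_tsv(data.frame(gene_set = "HLA_like", es = gs$es, nes = gs$nes,
                       p = gs$p, n_perm = gs$n_perm, n_set = gs$n_set),
            file.path(d, "gsea.tsv"))

  # Fisher enrichment of the HLA-like set among down-regulated genes, and
  # hyper/hypo counts over cluster probes.
  hla_genes <- ann$gene_sets$HLA_like
  in_hla <- stats::setNames(
    ifelse(de_g$feature %in% hla_genes, "HLA_like", "other"), de_g$feature)
  fe <- fisher_enrichment(down_mut, de_g$feature, in_hla)
  write_tsv(fe, file.path(d, "hla_fisher.tsv"))

  tab <- read_tsv(file.path(out_dir, "delta", "delta_mut.tsv"))
  mcalls <- tab[tab$mark == "m", ]
  cl <- mcalls[mcalls$probe %in% ann$cluster_probes, ]
  write_tsv(data.frame(hyper = sum(cl$call == "hyper"),
                       hypo = sum(cl$call == "hypo"),
                       n_cluster_probes = nrow(cl)),
            file.path(d, "hla_probe_calls.tsv"))

  # Methylation retention on 5mC (oxBS) betas -- BS total methylation is
  # blind to sites where compensating 5mC/5hmC shifts cancel -- comparing the
  # mutant baseline against the pooled treated time points. HLA-like set =
  # cluster probes called hypermethylated; global set = all called
  # differential 5mC probes.
  b <- read_pipeline_betas(out_dir)
  conds <- config$effects$conditions
  baseline <- subset_conditions(b$oxbs, conds[2])
  treated <- subset_conditions(b$oxbs, conds[3:4])
  hla_set <- cl$probe[cl$call == "hyper"]
  global_set <- mcalls$probe[mcalls$call != "none"]
  thr <- config$integration$retention_threshold
  rows <- lapply(list(hla = hla_set, global = global_set), function(s) {
    if (length(s) == 0) return(NULL)
    r <- methylation_retention(baseline, treated, s, thr)
    data.frame(n = r$n, mean_baseline = r$mean_baseline,
               mean_treated = r$mean_treated, mean_delta = r$mean_delta,
               retained_fraction = r$retained_fraction)
  })
  ret <- do.call(rbind, Filter(Negate(is.null), rows))
  ret <- cbind(set = names(Filter(Negate(is.null), rows)), ret)
  write_tsv(ret, file.path(d, "retention.tsv"))
  invisible(out_dir)
}

# The planted motif used by the synthetic motif stage: a crisp AP-1-like
# 8-mer (TGACTCAC) with 91% consensus bases.
planted_pwm <- function() {
  cons <- c("T", "G", "A", "C", "T", "C", "A", "C")
  mat <- matrix(0.03, length(cons), 4, dimnames = list(NULL, DNA_BASES))
  for (i in seq_along(cons)) mat[i, cons[i]] <- 0.91
  pwm(mat, id = "planted")
}

#' Motif stage: planted-motif enrichment on synthetic sequences
#'
#' Generates target sequences (standing in for de-regulated enhancer
#' sequences; the synthetic genome carries no nucleotide sequence) with the
#' planted motif at the configured fraction, a background set with a low
#' plant fraction, and a panel of random decoy PWMs, then runs
#' [motif_enrichment()].
#'
#' @inheritParams stage_simulate
#' @return The output directory, invisibly.
#' @export
stage_motifs <- function(config, out_dir) {
  d <- stage_dir(out_dir, "motifs")
  mc <- config$motifs
  seed <- config$seeds[["motifs"]]
  pw <- planted_pwm()
  targets <- plant_motif(
    random_sequences(mc$n_targets, mc$seq_width, seed = seed),
    pw, mc$plant_fraction_targets, seed = seed + 1L)
  background <- plant_motif(
    random_sequences(mc$n_background, mc$seq_width, seed = seed + 2L),
    pw, mc$plant_fraction_background, seed = seed + 3L)
  names(background) <- sprintf("b%04d", seq_along(background))
  pwms <- c(list(planted = pw), random_pwms(mc$n_decoys, nrow(pw$mat),
                                            seed = seed + 4L))
  write_fasta(targets, file.path(d, "targets.fa"))
  write_fasta(background, file.path(d, "background.fa"))
  write_pwms(pwms, file.path(d, "pwms.txt"))
  enr <- motif_enrichment(targets, background, pwms, mc$score_fraction)
  write_tsv(enr, file.path(d, "motif_enrichment.tsv"))
  invisible(out_dir)
}

#' Run the full pipeline
#'
#' Executes simulate, methylome, enrich, eRNAs, DE, integrate and motifs in
#' dependency order, then writes `summary.json` (the headline numbers of the
#' analysis, including truth-based recovery metrics) and `manifest.json`
#' (resolved config, seed expansions, file digests, row counts). A stage
#' failure aborts with the stage name; outputs of completed stages are kept.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `summary` and `manifest`.
#' @export
run_full <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(simulate = stage_simulate, methylome = stage_methylome,
                 enrich = stage_enrich, ernas = stage_ernas, de = stage_de,
                 integrate = stage_integrate, motifs = stage_motifs)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](config, out_dir),
             error = function(e) stopf("stage '%s' failed: %s", nm,
                                       conditionMessage(e)))
  }
  summary <- pipeline_summary(config, out_dir)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- pipeline_manifest(config, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, manifest = manifest))
}

pipeline_summary <- function(config, out_dir) {
  ann <- read_genome_annotation(file.path(out_dir, "annotation"))
  tab <- read_tsv(file.path(out_dir, "delta", "delta_mut.tsv"))
  h <- tab[tab$mark == "h", ]
  m <- tab[tab$mark == "m", ]
  truth_sets <- read_tsv(file.path(out_dir, "methylome", "truth_sets.tsv"))
  tset <- function(s) truth_sets$probe[truth_sets$set == s]
  h_true <- c(tset("loss_5hmc"), tset("gain_5hmc"))
  h_called <- h$probe[h$call != "none"]
  dir_ok <- c(h$probe[h$call == "hypo" & h$probe %in% tset("loss_5hmc")],
              h$probe[h$call == "hyper" & h$probe %in% tset("gain_5hmc")])
  cors <- read_tsv(file.path(out_dir, "delta", "correlations.tsv"))
  fe <- read_tsv(file.path(out_dir, "enrichment", "enrichment_feature.tsv"))
  units <- read_units_bed(file.path(out_dir, "ernas", "units.bed"))
  truth_e <- read_tsv(file.path(out_dir, "txn", "truth_ernas.tsv"))
  rec <- evaluate_erna_recovery(units, truth_e)
  de_g <- read_tsv(file.path(out_dir, "de", "de_genes_mut.tsv"))
  de_e <- read_tsv(file.path(out_dir, "de", "de_ernas_mut.tsv"))
  links <- read_tsv(file.path(out_dir, "integration", "ep_pairs.tsv"))
  ep_truth <- read_tsv(file.path(out_dir, "txn", "truth_ep_pairs.tsv"))
  ep_rec <- ep_pairs_recovered(links, units, ep_truth)
  ov <- read_tsv(file.path(out_dir, "integration", "reversal_overlap.tsv"))
  gs <- read_tsv(file.path(out_dir, "integration", "gsea.tsv"))
  hf <- read_tsv(file.path(out_dir, "integration", "hla_fisher.tsv"))
  hp <- read_tsv(file.path(out_dir, "integration", "hla_probe_calls.tsv"))
  ret <- read_tsv(file.path(out_dir, "integration", "retention.tsv"))
  getret <- function(s, col) {
    if (s %in% ret$set) ret[[col]][ret$set == s] else NA_real_
  }
  list(
    n_probes = length(unique(h$probe)),
    n_hyper_5mc_called = sum(m$call == "hyper"),
    n_hypo_5mc_called = sum(m$call == "hypo"),
    n_loss_5hmc_called = sum(h$call == "hypo"),
    n_gain_5hmc_called = sum(h$call == "hyper"),
    hmc_sensitivity = length(dir_ok) / length(h_true),
    hmc_fdr = if (length(h_called)) {
      sum(!h_called %in% h_true) / length(h_called)
    } else NA_real_,
    anticorr_r_mut = cors$r[cors$contrast == "mut"],
    anticorr_r_t4 = cors$r[cors$contrast == "t4"],
    anticorr_r_t7 = cors$r[cors$contrast == "t7"],
    enhancer_p_greater = fe$p_greater[fe$class == "enhancer"],
    promoter_p_less = fe$p_less[fe$class == "promoter"],
    n_ernas_annotated = sum(units$class == "eRNA"),
    erna_precision = rec$precision,
    erna_recall = rec$recall,
    n_de_genes_mut = sum(de_g$direction != "none"),
    n_genes_up_mut = sum(de_g$direction == "up"),
    n_genes_down_mut = sum(de_g$direction == "down"),
    n_de_ernas_mut = sum(de_e$direction != "none"),
    n_ep_pairs = nrow(links),
    ep_pair_recall = ep_rec,
    reversal_overlap = ov$overlap,
    reversal_overlap_p = ov$p,
    gsea_hla_es = gs$es, gsea_hla_nes = gs$nes, gsea_hla_p = gs$p,
    hla_fisher_p = hf$p_greater[hf$class == "HLA_like"],
    hla_hyper_probes = hp$hyper,
    hla_hypo_probes = hp$hypo,
    hla_retained_fraction = getret("hla", "retained_fraction"),
    global_retained_fraction = getret("global", "retained_fraction")
  )
}

# Fraction of planted E-P pairs recovered: a planted pair counts as
# recovered when some reported link joins its gene to an annotated eRNA unit
# overlapping the planted enhancer interval.
ep_pairs_recovered <- function(links, units, ep_truth) {
  if (!nrow(ep_truth)) return(NA_real_)
  if (!nrow(links)) return(0)
  eu <- units[match(links$enhancer, units$id), , drop = FALSE]
  got <- vapply(seq_len(nrow(ep_truth)), function(i) {
    cand <- which(links$gene == ep_truth$gene[i])
    if (!length(cand)) return(FALSE)
    any(eu$chrom[cand] == ep_truth$chrom[i] &
          eu$start[cand] < ep_truth$end[i] &
          eu$end[cand] > ep_truth$start[i] - 1)
  }, logical(1))
  mean(got)
}

pipeline_manifest <- function(config, out_dir) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        c("manifest.json")))
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  rows <- lapply(stats::setNames(nm = files[grepl("\\.tsv$|\\.bed$", files)]),
                 function(f) length(readLines(file.path(out_dir, f))))
  list(package_version = as.character(utils::packageVersion("methenh")),
       config = config$raw,
       seed = config$seed,
       stage_seeds = as.list(config$seeds),
       files = digests,
       row_counts = rows)
}
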