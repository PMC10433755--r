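#' Default study configuration
#'
#' A desk-scale analogue of a multi-assay enhancer study: a five-arm
#' synthetic genome, three assay-like peak sets with decreasing
#' sequence-signal quality, chromosome-fold cross-validation for each, a
#' cross-assay transfer of the first (STARR-like) model, and a simulated
#' dual-luciferase experiment.
#'
#' The three assay specs encode the geometry that separates strong from
#' weak sequence-activity association in real data: the STARR-like assay
#' has centered, near-ubiquitous motif signal; the DNase-like assay is
#' similar but slightly diluted; the H3K4me1-like assay has wider peaks,
#' motifs displaced from the summit, and weaker signal.
#'
#' @param seed global seed; all stage seeds are derived from it.
#' @param arm_length bp per chromosome arm (default 500 kb).
#' @param peak_count peaks per assay (default 1000).
#' @return nested configuration list.
#' @export
default_study_config <- function(seed = 1L, arm_length = 5e5,
                                 peak_count = 1000) {
  list(
    seed = as.integer(seed),
    genome = list(arm_length = arm_length, gc_content = 0.42),
    annotation = list(gene_count = 40),
    window_width = 501,
    assays = list(
      list(name = "STARR_like", peak_count = peak_count, width_mean = 150,
           width_sd = 40, signal_strength = 1.0, motifs_per_peak = 2,
           summit_offset_bp = 0),
      list(name = "DNase_like", peak_count = peak_count, width_mean = 150,
           width_sd = 40, signal_strength = 0.8, motifs_per_peak = 2,
           summit_offset_bp = 0),
      list(name = "H3K4me1_like", peak_count = peak_count, width_mean = 250,
           width_sd = 60, signal_strength = 0.5, motifs_per_peak = 2,
           summit_offset_bp = 350)
    ),
    model = list(k_min = 6, k_max = 8, n_members = 48, l2_alpha = 0.01,
                 max_epochs = 1000, tol = 1e-3),
    reference_assay = "STARR_like",
    luciferase = list(n_fragments = 20, active_fraction = 0.45,
                      mean_fold_activity = 4, replicate_cv = 0.15,
                      replicates = 6)
  )
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML path.
#' @return the configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_study_config(cfg)
  cfg
}

#' @rdname read_study_config
#' @param config configuration list.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_study_config <- function(config) {
  need <- c("seed", "genome", "assays", "model", "window_width")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("study config missing field(s): ", paste(miss, collapse = ", "))
  }
  if (length(config$assays) == 0) stop("study config lists zero assays")
  invisible(config)
}

#' Run the full desk-scale study
#'
#' Simulate genome and annotation; plant each assay's peaks; characterize
#' every peak set (count, widths, genome and element coverage); build each
#' labeled dataset and run chromosome-fold cross-validation; correlate
#' AUC with coverage, peak count and width across assays; train the
#' reference (STARR-like) enhancer model on all of its peaks and apply it
#' to every other assay, cross-tabulating predictions with overlap against
#' the reference peaks; and simulate plus analyze a dual-luciferase table,
#' comparing its active count with the model's predicted fraction by
#' binomial test. Deterministic given `config$seed`.
#'
#' @param config list from [default_study_config()] or
#'   [read_study_config()].
#' @param outdir optional directory; when given, all result tables are
#'   written there as TSV/JSON.
#' @return list with `peak_summaries`, `element_coverage`, `cv`,
#'   `auc_correlations`, `cross_assay`, `luciferase`, `manifest`.
#' @export
run_study <- function(config = default_study_config(), outdir = NULL) {
  validate_study_config(config)
  seed <- config$seed
  arms <- stats::setNames(rep(config$genome$arm_length, 5), FLY_ARMS)
  sim <- simulate_genome(arms, gc_content = config$genome$gc_content,
                         seed = derive_seed(seed, 101L))
  ann <- simulate_annotation(sim$genome,
                             gene_count = config$annotation$gene_count %||% 40,
                             seed = derive_seed(seed, 102L))
  sequences <- sim$sequences
  assay_out <- list()
  for (i in seq_along(config$assays)) {
    a <- config$assays[[i]]
    spec <- assay_sim_spec(a$name, a$peak_count, a$width_mean, a$width_sd,
                           a$signal_strength, a$motifs_per_peak,
                           a$summit_offset_bp,
                           seed = derive_seed(seed, 200L + i))
    planted <- plant_peaks(sequences, sim$genome, spec,
                           exclusions = ann$cds)
    sequences <- planted$sequences  # assays profile the same genome
    assay_out[[a$name]] <- planted
  }
  peak_summaries <- do.call(rbind, lapply(names(assay_out), function(nm) {
    summarize_peaks(assay_out[[nm]]$peaks, sim$genome, name = nm)
  }))
  elem_cov <- do.call(rbind, lapply(names(assay_out), function(nm) {
    ec <- element_coverage(assay_out[[nm]]$peaks, ann, sim$genome)
    ec$dataset <- nm
    ec[, c("dataset", "element", "fraction")]
  }))
  cv <- list()
  datasets <- list()
  for (i in seq_along(assay_out)) {
    nm <- names(assay_out)[i]
    ds <- build_dataset(assay_out[[nm]]$peaks, sequences, sim$genome,
                        cds = ann$cds, width = config$window_width,
                        seed = derive_seed(seed, 300L + i))
    datasets[[nm]] <- ds
    cv[[nm]] <- cross_validate(
      ds, k_min = config$model$k_min, k_max = config$model$k_max,
      n_members = config$model$n_members,
      l2_alpha = config$model$l2_alpha,
      max_epochs = config$model$max_epochs,
      tol = config$model$tol %||% 1e-3,
      seed = derive_seed(seed, 400L + i))
  }
  aucs <- vapply(cv, `[[`, numeric(1), "pooled_auc")
  cor_or_null <- function(x) {
    if (length(aucs) >= 3 && stats::sd(x) > 0 && stats::sd(aucs) > 0) {
      pearson_correlation_test(aucs, x)
    } else NULL  # undefined for a constant covariate
  }
  auc_correlations <- list(
    coverage = cor_or_null(peak_summaries$genome_coverage),
    peak_count = cor_or_null(peak_summaries$peak_count),
    width = cor_or_null(peak_summaries$width_mean))
  # Cross-assay transfer: reference model trained on ALL of its peaks.
  ref <- config$reference_assay %||% names(assay_out)[1]
  ref_ds <- datasets[[ref]]
  ref_model <- fit_kmer_ensemble(
    ref_ds$sequence, ref_ds$label,
    k_min = config$model$k_min, k_max = config$model$k_max,
    n_members = config$model$n_members, l2_alpha = config$model$l2_alpha,
    max_epochs = config$model$max_epochs, tol = config$model$tol %||% 1e-3,
    seed = derive_seed(seed, 500L))
  cross_assay <- list()
  for (nm in setdiff(names(assay_out), ref)) {
    preds <- apply_model(ref_model, assay_out[[nm]]$peaks, sequences)
    cross_assay[[nm]] <- overlap_breakdown(preds,
                                           assay_out[[ref]]$peaks)
  }
  luc <- NULL
  if (!is.null(config$luciferase)) {
    lc <- config$luciferase
    sim_luc <- simulate_luciferase(lc$n_fragments, lc$active_fraction,
                                   lc$mean_fold_activity, lc$replicate_cv,
                                   lc$replicates %||% 6,
                                   seed = derive_seed(seed, 600L))
    res <- luciferase_analysis(sim_luc$table)
    cmp <- if (length(cross_assay)) {
      pf <- cross_assay[[1]]$predicted_fraction / 100
      compare_to_luciferase(sum(res$significant), nrow(res), pf)
    } else NULL
    luc <- list(table = sim_luc$table, truth = sim_luc$truth,
                results = res, binomial_p_vs_model = cmp)
  }
  out <- list(peak_summaries = peak_summaries, element_coverage = elem_cov,
              cv = cv, auc_correlations = auc_correlations,
              cross_assay = cross_assay, luciferase = luc,
              manifest = list(seed = seed, config = config,
                              package_version =
                                as.character(utils::packageVersion("cresignal"))))
  if (!is.null(outdir)) write_study_outputs(out, outdir)
  out
}

write_study_outputs <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(outdir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(study$peak_summaries, "peak_summaries.tsv")
  wt(study$element_coverage, "element_coverage.tsv")
  auc_tab <- do.call(rbind, lapply(names(study$cv), function(nm) {
    x <- study$cv[[nm]]
    tibble::tibble(dataset = nm, pooled_auc = x$pooled_auc,
                   t(x$fold_auc))
  }))
  wt(auc_tab, "cv_auc.tsv")
  for (nm in names(study$cross_assay)) {
    rep <- study$cross_assay[[nm]]
    wt(rep$per_peak, paste0("crossassay_", nm, "_per_peak.tsv"))
    wt(tibble::tibble(dataset = nm, n_peaks = rep$n_peaks,
                      predicted_pct = rep$predicted_fraction,
                      t(rep$quadrants)),
       paste0("crossassay_", nm, "_summary.tsv"))
  }
  if (!is.null(study$luciferase)) {
    wt(study$luciferase$results, "luciferase_results.tsv")
  }
  jsonlite::write_json(study$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
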