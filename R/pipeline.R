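#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the field's
#' conventional defaults: localization probability > 0.75, adjusted-p
#' thresholds of 0.01 for the proteome and 0.05 for phosphosite
#' occupancies, confound flagging at fourfold protein change.
#'
#' @param mode `"comparison"` or `"timecourse"`.
#' @param loc_prob_min strict localization-probability threshold.
#' @param p_adj_proteome,p_adj_phospho adjusted-p significance thresholds.
#' @param min_peptides minimum peptides per protein ratio.
#' @param confound_threshold protein |log2FC| above which site occupancies
#'   are flagged as confounded.
#' @param min_overlap ORA minimum foreground overlap.
#' @param gsea_n_perm,gsea_weight,gsea_min_size GSEA settings.
#' @param seed seed for the permutation RNG.
#' @return list of class `silaf_config`.
#' @export
silaf_config <- function(mode = c("comparison", "timecourse"),
                         loc_prob_min = 0.75,
                         p_adj_proteome = 0.01, p_adj_phospho = 0.05,
                         min_peptides = 1, confound_threshold = 2,
                         min_overlap = 3, gsea_n_perm = 1000,
                         gsea_weight = 1, gsea_min_size = 5, seed = 1) {
  structure(list(mode = match.arg(mode), loc_prob_min = loc_prob_min,
                 p_adj_proteome = p_adj_proteome,
                 p_adj_phospho = p_adj_phospho, min_peptides = min_peptides,
                 confound_threshold = confound_threshold,
                 min_overlap = min_overlap, gsea_n_perm = gsea_n_perm,
                 gsea_weight = gsea_weight, gsea_min_size = gsea_min_size,
                 seed = seed, version = "silafkit 0.1.0"),
            class = "silaf_config")
}

# Noise-free (exactly zero-variance) inputs make a t-test meaningless;
# report every feature untested instead of failing the whole run.
.test_or_degenerate <- function(mat) {
  n <- rowSums(is.finite(mat))
  s2 <- apply(mat, 1, function(v) stats::var(v[is.finite(v)]))
  if (all(s2[n >= 2] == 0, na.rm = TRUE)) {
    out <- data.frame(
      feature_id = rownames(mat), n = as.integer(n),
      mean_log2fc = rowMeans(mat, na.rm = TRUE), s2 = s2,
      s2_post = NA_real_, t_mod = NA_real_, p = NA_real_, p_adj = NA_real_,
      tested = FALSE, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  moderated_t_test(mat)
}

.log_event <- function(log, stage, event, ...) {
  entry <- c(list(stage = stage, event = event), list(...))
  c(log, list(entry))
}

.maybe_read <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full quantification pipeline
#'
#' Comparison mode: flagged-group exclusion, per-run ratio normalization,
#' protein-level aggregation, moderated differential testing, site
#' filtering and occupancy changes with their own moderated test, and
#' (when gene sets / annotation are supplied) GSEA on the protein ranking,
#' ORA of the significant proteins, and per-category summaries.
#' Time-course mode: incorporation time course, turnover fits and
#' per-category labeling summaries. Deterministic given config and inputs.
#'
#' @param evidence evidence data.frame or TSV path.
#' @param protein_groups protein-groups data.frame or TSV path.
#' @param sites optional sites data.frame or TSV path (comparison mode).
#' @param annotation optional annotation data.frame or TSV path.
#' @param gene_sets optional gene sets ([read_gmt()]) or GMT path.
#' @param config a [silaf_config()].
#' @param out_dir optional output directory: all stage tables (TSV), a
#'   machine-readable `summary.json`, a JSON-lines `log.jsonl` of every
#'   filtering/normalization decision, and the config are written there.
#' @return list of class `silaf_run` with the stage outputs and `summary`.
#' @export
run_pipeline <- function(evidence, protein_groups, sites = NULL,
                         annotation = NULL, gene_sets = NULL,
                         config = silaf_config(), out_dir = NULL) {
  stopifnot(inherits(config, "silaf_config"))
  evidence <- .maybe_read(evidence, read_evidence)
  protein_groups <- .maybe_read(protein_groups, read_protein_groups)
  sites <- if (!is.null(sites)) .maybe_read(sites, read_sites)
  annotation <- if (!is.null(annotation)) .maybe_read(annotation, read_annotation)
  gene_sets <- if (!is.null(gene_sets)) .maybe_read(gene_sets, read_gmt)
  log <- list()

  pg_f <- filter_protein_groups(protein_groups)
  log <- .log_event(log, "filter", "protein_groups_excluded",
                    counts = as.list(attr(pg_f, "removed")))
  ev <- evidence[evidence$protein_group_id %in% pg_f$protein_group_id, ,
                 drop = FALSE]
  log <- .log_event(log, "filter", "evidence_retained",
                    n_in = nrow(evidence), n_out = nrow(ev))

  if (config$mode == "timecourse") {
    tc <- incorporation_timecourse(ev, annotation)
    fits <- fit_turnover_table(tc)
    final_tp <- max(tc$per_protein$timepoint_days)
    final <- tc$per_protein[tc$per_protein$timepoint_days == final_tp, ]
    cats <- if (!is.null(annotation))
      category_labeling_summary(final, annotation)
    summary <- list(
      mode = "timecourse",
      n_proteins_timecourse = length(unique(tc$per_protein$protein_group_id)),
      n_turnover_fits = nrow(fits),
      n_converged = sum(fits$converged),
      median_final_fraction = stats::median(final$fraction, na.rm = TRUE)
    )
    res <- structure(list(timecourse = tc, turnover = fits,
                          category_labeling = cats, summary = summary,
                          config = config, log = log),
                     class = "silaf_run")
    if (!is.null(out_dir)) .write_run(res, out_dir)
    return(res)
  }

  ev <- add_normalized_ratios(ev)
  log <- .log_event(log, "normalize", "median_shifts",
                    shifts = as.list(attr(ev, "shifts")))
  pq <- protein_log2fc(ev, min_peptides = config$min_peptides)
  log <- .log_event(log, "quant", "proteins_quantified", n = nrow(pq),
                    dropped = length(attr(pq, "dropped")))

  mat <- as.matrix(pq[, grep("^log2fc_b", names(pq)), drop = FALSE])
  rownames(mat) <- pq$protein_group_id
  prot_tests <- .test_or_degenerate(mat)
  prot_tests <- significance_tables(prot_tests, config$p_adj_proteome)
  log <- .log_event(log, "test", "proteome_significance",
                    counts = as.list(attr(prot_tests, "counts")),
                    d0 = attr(prot_tests, "d0"))

  site_quant <- NULL; site_tests <- NULL
  n_sites_detected <- 0L; n_sites_quantified <- 0L
  if (!is.null(sites)) {
    n_sites_detected <- nrow(sites)
    sf <- filter_sites(sites, config$loc_prob_min)
    log <- .log_event(log, "phospho", "localization_filter",
                      n_in = nrow(sites), n_out = nrow(sf),
                      removed = attr(sf, "removed"))
    site_quant <- site_occupancy(sf, pq)
    site_quant <- flag_protein_confound(site_quant, pq,
                                        config$confound_threshold)
    occ_mat <- as.matrix(site_quant[, grep("^occ_b", names(site_quant)),
                                    drop = FALSE])
    rownames(occ_mat) <- site_quant$site_id
    n_sites_quantified <- sum(rowSums(is.finite(occ_mat)) >= 2)
    site_tests <- .test_or_degenerate(occ_mat)
    site_tests <- significance_tables(site_tests, config$p_adj_phospho)
    log <- .log_event(log, "phospho", "occupancy_significance",
                      counts = as.list(attr(site_tests, "counts")))
  }

  enr <- list(gsea = NULL, ora = NULL, categories = NULL)
  if (!is.null(gene_sets)) {
    enr$gsea <- gsea(pq$protein_group_id, pq$mean_log2fc, gene_sets,
                     n_perm = config$gsea_n_perm, weight = config$gsea_weight,
                     min_size = config$gsea_min_size, seed = config$seed)
    sig_ids <- prot_tests$feature_id[prot_tests$significant]
    enr$ora <- if (length(sig_ids))
      ora(sig_ids, pq$protein_group_id, gene_sets,
          min_overlap = config$min_overlap)
  }
  if (!is.null(annotation))
    enr$categories <- category_boxplot_summary(
      data.frame(protein_id = pq$protein_group_id, value = pq$mean_log2fc,
                 stringsAsFactors = FALSE), annotation)

  counts <- attr(prot_tests, "counts")
  summary <- list(
    mode = "comparison",
    n_protein_groups_input = nrow(protein_groups),
    n_protein_groups_excluded = unname(attr(pg_f, "removed")["total"]),
    n_proteins_quantified = nrow(pq),
    n_significant_up = unname(counts["up"]),
    n_significant_down = unname(counts["down"]),
    n_sites_detected = n_sites_detected,
    n_sites_localized = if (!is.null(site_quant)) nrow(site_quant) else 0L,
    n_sites_quantified_occupancy = n_sites_quantified,
    n_sites_significant = if (!is.null(site_tests))
      sum(site_tests$significant) else 0L
  )
  res <- structure(list(protein_quant = pq, protein_tests = prot_tests,
                        site_quant = site_quant, site_tests = site_tests,
                        enrichment = enr, summary = summary, config = config,
                        log = log),
                   class = "silaf_run")
  if (!is.null(out_dir)) .write_run(res, out_dir)
  res
}

.write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(res$config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(vapply(res$log, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)), ""),
    file.path(out_dir, "log.jsonl"))
  tabs <- list(protein_quant = res$protein_quant,
               protein_tests = res$protein_tests,
               site_quant = res$site_quant, site_tests = res$site_tests,
               gsea = res$enrichment$gsea, ora = res$enrichment$ora,
               categories = res$enrichment$categories,
               turnover = res$turnover,
               timecourse = if (!is.null(res$timecourse))
                 res$timecourse$per_protein)
  for (nm in names(tabs))
    if (!is.null(tabs[[nm]]))
      write_results_tsv(tabs[[nm]], file.path(out_dir, paste0(nm, ".txt")))
  invisible(out_dir)
}

#' @export
print.silaf_run <- function(x, ...) {
  cat("silaf_run (", x$summary$mode, ")\n", sep = "")
  for (nm in names(x$summary))
    cat(sprintf("  %s: %s\n", nm, x$summary[[nm]]))
  invisible(x)
}

#' Score a pipeline run against the simulated ground truth
#'
#' Recovery metrics per stage: mean absolute error of protein log2 fold
#' changes, sign agreement of significant calls on truly changed proteins,
#' empirical FDR and sensitivity at the phospho-convention adjusted-p
#' threshold of 0.05, mean bias of site occupancy changes, and (time-course
#' runs) the median relative error of fitted turnover rates. Each metric is
#' compared against a configurable tolerance.
#'
#' @param run a `silaf_run`.
#' @param ground_truth the `silaf_ground_truth` that generated the inputs.
#' @param tolerances named list of tolerances overriding the defaults.
#' @return data.frame of class `silaf_recovery` (`metric`, `value`,
#'   `tolerance`, `comparison`, `pass`) with `attr(, "pass")` the overall
#'   verdict.
#' @export
score_recovery <- function(run, ground_truth,
                           tolerances = list()) {
  tol <- utils::modifyList(list(log2fc_mae = 0.1, occupancy_bias = 0.05,
                                k_median_rel_err = 0.05, empirical_fdr = 0.1,
                                sensitivity = 0.8, sign_agreement = 0.95),
                           tolerances)
  gt <- ground_truth
  stopifnot(inherits(run, "silaf_run"), inherits(gt, "silaf_ground_truth"))
  rows <- list()
  add <- function(metric, value, tolerance, comparison) {
    pass <- if (comparison == "le") value <= tolerance else value >= tolerance
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, value = value, tolerance = tolerance,
      comparison = comparison, pass = pass, stringsAsFactors = FALSE)
  }

  if (run$summary$mode == "comparison") {
    pq <- run$protein_quant
    if (!all(pq$protein_group_id %in% gt$proteins$protein_id))
      stop("ground truth does not match run: unknown protein ids")
    truth <- gt$proteins$true_log2fc[match(pq$protein_group_id,
                                           gt$proteins$protein_id)]
    add("log2fc_mae", mean(abs(pq$mean_log2fc - truth)), tol$log2fc_mae, "le")

    tests <- run$protein_tests
    tt <- merge(tests, data.frame(feature_id = gt$proteins$protein_id,
                                  true_log2fc = gt$proteins$true_log2fc),
                by = "feature_id")
    sig05 <- !is.na(tt$p_adj) & tt$p_adj < 0.05
    is_de <- tt$true_log2fc != 0
    inference_done <- any(!is.na(tt$p_adj))
    if (any(sig05))
      add("empirical_fdr", sum(sig05 & !is_de) / sum(sig05),
          tol$empirical_fdr, "le")
    if (inference_done && any(is_de)) {
      add("sensitivity", sum(sig05 & is_de) / sum(is_de),
          tol$sensitivity, "ge")
      hit <- sig05 & is_de
      if (any(hit))
        add("sign_agreement",
            mean(sign(tt$mean_log2fc[hit]) == sign(tt$true_log2fc[hit])),
            tol$sign_agreement, "ge")
    }

    if (!is.null(run$site_quant) && nrow(gt$phosphosites)) {
      sq <- run$site_quant
      key <- sprintf("%s_%s%d", gt$phosphosites$protein_id,
                     gt$phosphosites$residue, gt$phosphosites$position)
      m <- match(sq$site_id, key)
      ok <- !is.na(m) & !is.na(sq$mean_log2_occupancy_change) & !sq$confounded
      if (any(ok))
        add("occupancy_bias",
            abs(mean(sq$mean_log2_occupancy_change[ok] -
                       gt$phosphosites$true_log2_occ_ratio[m[ok]])),
            tol$occupancy_bias, "le")
    }
  } else {
    fits <- run$turnover
    if (!all(fits$protein_id %in% gt$proteins$protein_id))
      stop("ground truth does not match run: unknown protein ids")
    ktrue <- gt$proteins$turnover_rate_k[match(fits$protein_id,
                                               gt$proteins$protein_id)]
    ok <- fits$converged
    add("k_median_rel_err",
        stats::median(abs(fits$k_hat[ok] - ktrue[ok]) / ktrue[ok]),
        tol$k_median_rel_err, "le")
  }

  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("silaf_recovery", class(out))
  out
}
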