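#' Behavioural validation report
#'
#' Computes the convergent-validity statistics for a scores table:
#' two-tailed Pearson r between CWF and CIU, correlations of each with
#' severity when a severity column is present, and a pooled-variance t-test
#' between two named aphasia subtype groups when a subtype column is
#' present (defaults: anomic vs broca, the fluent/non-fluent contrast).
#'
#' @param scores data.frame with columns `CWF`, `CIU`, optionally
#'   `severity` and `aphasia_type`.
#' @param groups two subtype labels to contrast.
#' @return list with `r_cwf_ciu`, optionally `r_severity_cwf`,
#'   `r_severity_ciu`, and `t_test` (list t/df/p plus group sizes).
#' @export
validation_report <- function(scores, groups = c("anomic", "broca")) {
  if (!all(c("CWF", "CIU") %in% names(scores)))
    stop_invalid("scores table needs CWF and CIU columns")
  ok <- stats::complete.cases(scores$CWF, scores$CIU)
  if (sum(ok) < 3) stop_invalid("insufficient data: fewer than 3 complete rows")
  out <- list(r_cwf_ciu = pearson(scores$CWF[ok], scores$CIU[ok]))
  if ("severity" %in% names(scores)) {
    out$r_severity_cwf <- pearson(scores$severity, scores$CWF)
    out$r_severity_ciu <- pearson(scores$severity, scores$CIU)
  }
  if ("aphasia_type" %in% names(scores)) {
    ga <- scores$CWF[scores$aphasia_type == groups[1]]
    gb <- scores$CWF[scores$aphasia_type == groups[2]]
    if (length(ga) >= 2 && length(gb) >= 2) {
      tt <- pooled_t_test(ga, gb)
      tt$groups <- stats::setNames(c(length(ga), length(gb)), groups)
      out$t_test <- tt
      gac <- scores$CIU[scores$aphasia_type == groups[1]]
      gbc <- scores$CIU[scores$aphasia_type == groups[2]]
      out$t_test_ciu <- pooled_t_test(gac, gbc)
    }
  }
  out
}

read_run_config <- function(path_or_list) {
  cfg <- if (is.character(path_or_list)) yaml::read_yaml(path_or_list)
  else path_or_list
  has_sim <- !is.null(cfg$simulate)
  has_real <- !is.null(cfg$inputs)
  if (has_sim == has_real)
    stop_invalid("config must contain exactly one of `simulate` or `inputs`")
  if (has_real) {
    paths <- unlist(cfg$inputs, use.names = TRUE)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_invalid("config error, missing inputs: ",
                   paste(missing, collapse = ", "))
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates score -> validate -> IRT -> psycholinguistic regression ->
#' lesion-symptom mapping suite from one configuration, either a
#' `simulate:` block (forwarded to [simulation_config()]) or an `inputs:`
#' block of file paths (`transcripts` directory, `checklist`, optionally
#' `lesions` directory, `atlas`, `streamlines`, `behaviour`). Lesion stages
#' are skipped, with a logged notice, when no lesion inputs are present.
#' A manifest records seeds, inputs and package version; identical configs
#' reproduce identical bundles.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @param out_dir optional directory for report tables and the manifest.
#' @param irt_models models to fit (default 1PL/2PL/3PL; set to `"1PL"` to
#'   shorten large runs).
#' @param verbose print per-stage progress.
#' @return object of class `report_bundle` with elements `cohort_summary`,
#'   `validation`, `irt_summary`, `regression_summary`, `lsm_summary`,
#'   `tract_summary`, `pvc_summary`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         irt_models = c("1PL", "2PL", "3PL"),
                         verbose = FALSE) {
  cfg <- read_run_config(config)
  note <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_invalid(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e))))
  }

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$grid_shape <- unlist(sim_args$grid_shape %||% c(32, 32, 32))
    scfg <- do.call(simulation_config, sim_args)
    note("simulate: n = %d", scfg$n_participants)
    cohort <- stage("simulate", generate_cohort(scfg))
    checklist <- cohort$checklist
    transcripts <- cohort$transcripts
    lesions <- cohort$lesions
    atlas <- cohort$tract_atlas
    streamlines <- cohort$streamlines
    behavior <- cohort$behavior
    scores <- cohort$cwf_results
    seed <- scfg$seed
  } else {
    inp <- cfg$inputs
    seed <- cfg$seed %||% 1L
    checklist <- stage("load", read_checklist(inp$checklist))
    tfiles <- list.files(inp$transcripts, pattern = "\\.tsv$", full.names = TRUE)
    transcripts <- stage("load", lapply(tfiles, read_transcript_tsv))
    scores <- stage("score", lapply(transcripts, score_cwf, checklist = checklist))
    behavior <- data.frame(
      participant_id = vapply(transcripts, `[[`, character(1), "participant_id"),
      CWF = vapply(scores, `[[`, integer(1), "total"),
      CIU = vapply(transcripts, count_cius, integer(1)),
      word_count = vapply(transcripts, word_count, integer(1)),
      stringsAsFactors = FALSE)
    if (!is.null(inp$behaviour)) {
      extra <- utils::read.delim(inp$behaviour, stringsAsFactors = FALSE)
      behavior <- merge(behavior, extra, by = "participant_id",
                        all.x = TRUE, sort = FALSE)
    }
    lesions <- NULL; atlas <- NULL; streamlines <- NULL
    if (!is.null(inp$lesions)) {
      lfiles <- list.files(inp$lesions, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE)
      vols <- lapply(lfiles, read_lesion_nifti)
      lesions <- cohort_lesions(sub("\\.nii(\\.gz)?$", "", basename(lfiles)),
                                vols)
    }
    if (!is.null(inp$atlas)) atlas <- read_tract_atlas_json(inp$atlas)
    if (!is.null(inp$streamlines))
      streamlines <- read_streamlines_json(inp$streamlines)
  }

  note("validate: %d participants", nrow(behavior))
  validation <- stage("validate", validation_report(behavior))

  irt_summary <- NULL
  rm_irt <- stage("response-matrix",
                  tryCatch(response_matrix(scores, checklist, for_irt = TRUE),
                           error = function(e) NULL))
  if (!is.null(rm_irt) && ncol(rm_irt$data) >= 2 && nrow(rm_irt$data) >= 10) {
    note("irt: %d items retained (%d dropped)", ncol(rm_irt$data),
         length(rm_irt$dropped_items))
    fits <- stage("irt", lapply(irt_models, function(m)
      fit_irt(rm_irt, m, max_iter = 300, tol = 1e-5)))
    names(fits) <- irt_models
    comparisons <- list()
    if (all(c("1PL", "2PL") %in% irt_models))
      comparisons$`1PL_vs_2PL` <- compare_models(fits$`1PL`, fits$`2PL`)
    if (all(c("1PL", "3PL") %in% irt_models))
      comparisons$`1PL_vs_3PL` <- compare_models(fits$`1PL`, fits$`3PL`)
    m2 <- stage("irt", m2_statistic(fits[[1]], rm_irt))
    irt_summary <- list(fits = fits, comparisons = comparisons, m2 = m2,
                        wright_map = item_person_map(fits[[1]]),
                        dropped_items = rm_irt$dropped_items)
  } else note("irt: skipped (matrix too small after degeneracy filtering)")

  item_totals <- Reduce(`+`, lapply(scores, `[[`, "per_item_counts"))
  regression_summary <- if (nrow(checklist$items) >= 6)
    stage("regression", psycholinguistic_regression(item_totals, checklist))
  else NULL

  lsm_summary <- NULL; tract_summary <- NULL; pvc_summary <- NULL
  if (!is.null(lesions) && length(lesions$subjects) >= 10) {
    note("lsm: %d subjects with masks", length(lesions$subjects))
    voxels <- stage("lsm", voxel_coverage_filter(lesions, 0.10))
    X <- lesion_matrix(lesions, voxels)
    cwf_res <- regress_out(behavior$CWF, lesions$lesion_size_cc)
    ciu_res <- regress_out(behavior$CIU, lesions$lesion_size_cc)
    lsm_cwf <- stage("lsm", sparse_cca_lsm(X, cwf_res, sparseness = -0.3,
                                           folds = 4, seed = seed,
                                           grid = lesions$grid))
    lsm_ciu <- stage("lsm", sparse_cca_lsm(X, ciu_res, sparseness = -0.3,
                                           folds = 4, seed = seed,
                                           grid = lesions$grid))
    lsm_summary <- list(CWF = lsm_cwf, CIU = lsm_ciu,
                        regions_cwf = if (!is.null(atlas))
                          label_weights(lsm_cwf, atlas) else NULL,
                        regions_ciu = if (!is.null(atlas))
                          label_weights(lsm_ciu, atlas) else NULL)
    if (!is.null(streamlines)) {
      disc <- lapply(lesions$volumes, disconnection_map,
                     streamlines = streamlines)
      dvols <- lapply(disc, function(d)
        lesion_volume(d$binary, lesions$volumes[[1]]$voxel_size_mm,
                      "disconnection"))
      dcoh <- cohort_lesions(lesions$subjects, dvols)
      dvox <- voxel_coverage_filter(dcoh, 0.10)
      if (length(dvox) >= 5) {
        Xd <- lesion_matrix(dcoh, dvox)
        lsm_summary$disconnection_CWF <-
          sparse_cca_lsm(Xd, cwf_res, sparseness = -0.3, folds = 4,
                         seed = seed, grid = lesions$grid)
        lsm_summary$disconnection_CIU <-
          sparse_cca_lsm(Xd, ciu_res, sparseness = -0.3, folds = 4,
                         seed = seed, grid = lesions$grid)
      }
    }
    if (!is.null(atlas)) {
      loads <- t(vapply(lesions$volumes, tract_lesion_percentage,
                        numeric(length(atlas$tracts)), tract_atlas = atlas))
      tract_summary <- do.call(rbind, lapply(colnames(loads), function(nm) {
        # a tract untouched (or engulfed) across the whole cohort has no
        # estimable partial correlation; report NA rather than aborting
        safe_pc <- function(yv) tryCatch(
          partial_correlation(loads[, nm], yv,
                              cbind(lesion_size = lesions$lesion_size_cc),
                              tails = "one"),
          error = function(e) list(r = NA_real_, p = NA_real_))
        pc_cwf <- safe_pc(behavior$CWF)
        pc_ciu <- safe_pc(behavior$CIU)
        data.frame(tract = nm, r_cwf = pc_cwf$r, p_cwf = pc_cwf$p,
                   r_ciu = pc_ciu$r, p_ciu = pc_ciu$p,
                   stringsAsFactors = FALSE)
      }))
    }
    pvc_summary <- stage("pvc", pvc(X, scale(cwf_res)[, 1], scale(ciu_res)[, 1],
                                    sparseness = -0.3, folds = 4, seed = seed,
                                    grid = lesions$grid))
  } else note("lsm: skipped (no lesion inputs)")

  cohort_summary <- list(
    n = nrow(behavior),
    cwf = summary(behavior$CWF), ciu = summary(behavior$CIU),
    word_count = summary(behavior$word_count),
    subtype_counts = if ("aphasia_type" %in% names(behavior))
      table(behavior$aphasia_type) else NULL,
    lesion_size_cc = if (!is.null(lesions)) summary(lesions$lesion_size_cc)
    else NULL)

  manifest <- list(seed = seed,
                   package_version =
                     as.character(utils::packageVersion("discoursemap")),
                   config = cfg, n_participants = nrow(behavior))
  bundle <- structure(list(cohort_summary = cohort_summary,
                           validation = validation,
                           irt_summary = irt_summary,
                           regression_summary = regression_summary,
                           lsm_summary = lsm_summary,
                           tract_summary = tract_summary,
                           pvc_summary = pvc_summary,
                           manifest = manifest),
                      class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, behavior, out_dir)
  bundle
}

write_report_bundle <- function(bundle, behavior, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(behavior, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  v <- bundle$validation
  summ <- list(
    r_cwf_ciu = round(v$r_cwf_ciu$r, 2),
    p_cwf_ciu = round(v$r_cwf_ciu$p, 4),
    m2 = if (!is.null(bundle$irt_summary))
      list(statistic = bundle$irt_summary$m2$statistic,
           df = bundle$irt_summary$m2$df, p = bundle$irt_summary$m2$p)
    else NULL,
    pvc = if (!is.null(bundle$pvc_summary))
      list(aic_difference = bundle$pvc_summary$aic_difference,
           verdict = bundle$pvc_summary$verdict) else NULL,
    manifest = bundle$manifest)
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(bundle$tract_summary))
    utils::write.table(bundle$tract_summary,
                       file.path(out_dir, "tract_partial_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Discourse analysis report\n")
  cat(sprintf("  participants: %d\n", x$cohort_summary$n))
  cat(sprintf("  r(CWF, CIU) = %.2f (p = %.4g)\n",
              x$validation$r_cwf_ciu$r, x$validation$r_cwf_ciu$p))
  if (!is.null(x$validation$t_test))
    cat(sprintf("  subtype t-test: t = %.1f (df %d), p = %.4g\n",
                x$validation$t_test$t, x$validation$t_test$df,
                x$validation$t_test$p))
  if (!is.null(x$irt_summary))
    cat(sprintf("  M2(%d) = %.1f, p = %.3f\n", x$irt_summary$m2$df,
                x$irt_summary$m2$statistic, x$irt_summary$m2$p))
  if (!is.null(x$pvc_summary))
    cat(sprintf("  PVC: AIC difference = %.1f -> %s\n",
                x$pvc_summary$aic_difference, x$pvc_summary$verdict))
  invisible(x)
}
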