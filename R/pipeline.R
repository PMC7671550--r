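#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' defaults used throughout the package: a 37.5% missingness cut-off,
#' candidate interior-knot counts 5/10/15/20 with spline orders 4 and 6,
#' the lambda grid `10^g` for `g` in \[-30, 20\] step 0.05, fuzziness
#' `f = 1.5`, fuzzy-silhouette weighting `gamma = 1`, significance level
#' `alpha = 0.05` and 10000 permutations for the pollen association.
#'
#' @param missing_cutoff Missing-fraction cut-off for patient inclusion.
#' @param drop_constant Exclude zero-variance recorders.
#' @param q_options,m_options Grid-search candidates for interior knots
#'   and spline order.
#' @param g_min,g_max,g_step Base-10 exponent grid for lambda.
#' @param parsimony_tol TGCV slack for preferring a simpler basis.
#' @param f Fuzziness exponent.
#' @param k Number of clusters, or `NULL` to choose by fuzzy silhouette.
#' @param k_range Candidate k when `k` is `NULL`.
#' @param n_starts,tol,max_iter Clustering control parameters.
#' @param gamma Fuzzy-silhouette weighting exponent.
#' @param k_tolerance FS slack for reporting near-best k.
#' @param alpha,n_perm Pollen-association test level and permutation
#'   count.
#' @param seed Integer seed governing every random draw in the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(missing_cutoff = 0.375, drop_constant = TRUE,
                            q_options = c(5L, 10L, 15L, 20L),
                            m_options = c(4L, 6L),
                            g_min = -30, g_max = 20, g_step = 0.05,
                            parsimony_tol = 0, f = 1.5, k = NULL,
                            k_range = 2:7, n_starts = 30L, tol = 1e-6,
                            max_iter = 1000L, gamma = 1,
                            k_tolerance = 0.05, alpha = 0.05,
                            n_perm = 10000L, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(log, stage, t0, con = NULL) {
  line <- sprintf("[%s] %s (%.2fs)", format(Sys.time(), "%H:%M:%S"),
                  stage, as.numeric(Sys.time()) - t0)
  message(line)
  if (!is.null(con)) writeLines(line, con)
  c(log, line)
}

#' Run the full analysis pipeline
#'
#' Scores raw daily records into CSMS series, filters and imputes the
#' cohort, normalizes to \[0, 1\], selects the shared penalized B-spline
#' basis by the TGCV grid search, clusters the coefficients with fuzzy
#' k-medoids (choosing k by the fuzzy silhouette when not fixed), and —
#' when pollen counts are supplied — smooths the normalized pollen curves
#' with the same basis and computes the ARp association table with its
#' cluster summary. All randomness is governed by `config$seed`, so a
#' rerun with the same inputs and seed reproduces every output.
#'
#' @param records Long-format daily record data frame (see
#'   [score_records()]), or `NULL` if `scores` is given.
#' @param pollen Optional taxa-by-days pollen count matrix on the same
#'   window.
#' @param config A [pipeline_config()].
#' @param scores Optional pre-scored patient-by-day raw CSMS matrix,
#'   bypassing the scoring stage.
#' @param output_dir Optional directory; when given, every artifact
#'   (scores, exclusion log, grid-search table, coefficients, partition,
#'   validity table, ARp tables, log, config snapshot) is written there as
#'   delimited text.
#' @return List of class `pipeline_result` with elements `scores` (raw),
#'   `filtered`, `imputed` (normalized), `grid_search`, `selection`
#'   (per-k validity, or `NULL` when k fixed), `partition`, `k`, `arp`,
#'   `arp_summary`, `config`, `log`.
#' @export
run_pipeline <- function(records = NULL, pollen = NULL,
                         config = pipeline_config(), scores = NULL,
                         output_dir = NULL) {
  t0 <- as.numeric(Sys.time())
  log <- character(0)
  con <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(output_dir, "pipeline.log"), open = "wt")
    on.exit(close(con), add = TRUE)
    dput(unclass(config), file.path(output_dir, "config.txt"))
  }
  run_stage <- function(stage, expr) {
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    log <<- stage_log(log, stage, t0, con)
    out
  }
  set.seed(config$seed)

  if (is.null(scores))
    scores <- run_stage("score", score_records(records))
  filtered <- run_stage("filter", filter_cohort(
    scores, cutoff = config$missing_cutoff,
    drop_constant = config$drop_constant))
  imputed <- run_stage("impute+normalize",
                       normalize_csms(impute_scores(filtered$scores)))
  grid <- seq(config$g_min, config$g_max, by = config$g_step)
  gs <- run_stage("tgcv_grid_search", tgcv_grid_search(
    imputed, q_options = config$q_options, m_options = config$m_options,
    grid = grid, parsimony_tol = config$parsimony_tol))

  C <- gs$coefficients
  selection <- NULL
  if (is.null(config$k)) {
    k_range <- config$k_range[config$k_range < nrow(C)]
    selection <- run_stage("select_k", select_k(
      C, k_range = k_range, f = config$f, gamma = config$gamma,
      tolerance = config$k_tolerance, n_starts = config$n_starts,
      tol = config$tol, max_iter = config$max_iter, seed = config$seed))
    k <- selection$best_k
    partition <- selection$partitions[[as.character(k)]]
  } else {
    k <- config$k
    partition <- run_stage("fkmed", fkmed(
      C, k = k, f = config$f, n_starts = config$n_starts,
      tol = config$tol, max_iter = config$max_iter, seed = config$seed))
  }

  arp <- arp_summary <- NULL
  if (!is.null(pollen)) {
    pollen_coefs <- run_stage("smooth_pollen", {
      pn <- normalize_pollen(pollen[, colnames(imputed), drop = FALSE])
      f0 <- fit_cohort_once(pn, as.numeric(colnames(imputed)), gs$spec,
                            gs$lambda)
      P <- f0$C
      rownames(P) <- rownames(pollen)
      P
    })
    arp <- run_stage("arp", arp_index(
      C, pollen_coefs, alpha = config$alpha, n_perm = config$n_perm,
      seed = config$seed))
    arp_summary <- cluster_arp_summary(arp, partition$U)
  }

  if (!is.null(output_dir)) {
    write_score_series(scores, file.path(output_dir, "scores_raw.tsv"))
    write_exclusion_log(filtered, file.path(output_dir, "exclusions.tsv"))
    write_score_series(imputed, file.path(output_dir, "scores_imputed.tsv"))
    utils::write.table(gs$table, file.path(output_dir, "grid_search.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_coefficients(C, file.path(output_dir, "coefficients.tsv"))
    write_partition(partition, file.path(output_dir, "partition.tsv"))
    if (!is.null(selection))
      write_validity_table(selection, file.path(output_dir, "validity.tsv"))
    if (!is.null(arp))
      write_arp_table(arp, file.path(output_dir, "arp.tsv"),
                      summary = arp_summary,
                      summary_path = file.path(output_dir, "arp_summary.tsv"))
  }

  structure(list(scores = scores, filtered = filtered, imputed = imputed,
                 grid_search = gs, selection = selection,
                 partition = partition, k = k, arp = arp,
                 arp_summary = arp_summary, config = config, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline: %d patients retained, basis m = %d / q = %d, k = %d\n",
              nrow(x$imputed), x$grid_search$selected$m,
              x$grid_search$selected$q, x$k))
  print(x$partition)
  if (!is.null(x$arp_summary)) {
    cat("Cluster mean ARp:\n")
    print(round(x$arp_summary$mean_arp, 3))
  }
  invisible(x)
}

#' Partition stability under alternative preprocessing and basis choices
#'
#' Reruns the pipeline with each missingness cut-off in `cutoffs` (and,
#' optionally, alternative `(q, m)` bases) and reports the adjusted Rand
#' index between every rerun's hardened partition and the reference run's,
#' on the patients common to both.
#'
#' @param records,pollen,config As in [run_pipeline()].
#' @param cutoffs Cut-off values to try (default `c(0.25, 0.375, 0.5)`).
#' @param alt_qm Optional list of `c(q, m)` pairs forcing a single basis.
#' @return Data frame with columns `variant`, `n`, `k`, `ARI`.
#' @export
sensitivity_analysis <- function(records, pollen = NULL,
                                 config = pipeline_config(),
                                 cutoffs = c(0.25, 0.375, 0.5),
                                 alt_qm = NULL) {
  ref <- run_pipeline(records, config = config)
  ref_lab <- stats::setNames(hard_labels(ref$partition),
                             rownames(ref$imputed))
  cfg_k <- config; cfg_k$k <- ref$k      # compare at the reference k
  variants <- list()
  for (co in cutoffs) {
    cfg <- cfg_k; cfg$missing_cutoff <- co
    variants[[sprintf("cutoff=%g", co)]] <- cfg
  }
  if (!is.null(alt_qm)) for (qm in alt_qm) {
    cfg <- cfg_k; cfg$q_options <- qm[1L]; cfg$m_options <- qm[2L]
    variants[[sprintf("q=%d,m=%d", qm[1L], qm[2L])]] <- cfg
  }
  rows <- lapply(names(variants), function(nm) {
    res <- run_pipeline(records, config = variants[[nm]])
    lab <- stats::setNames(hard_labels(res$partition), rownames(res$imputed))
    common <- intersect(names(lab), names(ref_lab))
    data.frame(variant = nm, n = length(common), k = res$k,
               ARI = adjusted_rand_index(ref_lab[common], lab[common]))
  })
  do.call(rbind, rows)
}
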