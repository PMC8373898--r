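# End-to-end pipeline: region super learner -> stimulus decoding (with and
# without alignment) -> four-class ensemble -> group RSA -> connectome, on a
# synthetic or on-disk cohort, with optional file outputs.

#' Run the full decoding pipeline
#'
#' Chains every stage on one cohort: nested region search for the
#' group-discriminative region, stimulus decoding on the winning region with
#' and without shared-response alignment, the coupled four-class ensemble,
#' condition-beta estimation with the grouped Mann-Whitney comparison and
#' RSMs, and the region-correlation connectome seeded at the winning region.
#'
#' The default grid is a single boosted-logistic configuration so the demo
#' finishes in minutes; pass `grid = hyper_grid()` for the full study grid.
#'
#' @param cohort A [generate_cohort()] result or a directory written by
#'   [write_cohort()]; `NULL` generates one from `spec`.
#' @param spec [cohort_spec()] used when `cohort` is `NULL`.
#' @param grid [hyper_grid()] for the region search.
#' @param k Shared-space dimension for the stimulus decoder.
#' @param threshold Absolute connectome threshold (study value 0.6).
#' @param seed Root seed fanned out to every stochastic stage.
#' @param outer_k,inner_k Cross-validation fold counts.
#' @param out_dir Optional directory for TSV/CSV/JSON outputs.
#' @return An object of class `anx_pipeline` with each stage's fit and a
#'   `summary` list of headline metrics.
#' @export
run_pipeline <- function(cohort = NULL, spec = cohort_spec(),
                         grid = hyper_grid(n_estimators = 10, learning_rate = 1,
                                           max_iterations = 100, penalty = "l2",
                                           C = 1),
                         k = 3, threshold = 0.6, seed = 1,
                         outer_k = 5, inner_k = 5, out_dir = NULL) {
  if (is.null(cohort)) {
    spec$seed <- sub_seed(seed, 1L)
    cohort <- generate_cohort(spec)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  ds <- if (!is.null(cohort$spec)) cohort_dataset(cohort)
        else assemble_dataset(cohort$runs, cohort$atlas, cohort$events,
                              cohort$metadata, volumes_per_block = 3, t_target = 35)

  sl <- nested_region_search(ds, grid = grid, outer_k = outer_k,
                             inner_k = inner_k, seed = sub_seed(seed, 2L))
  top_region <- sl$ranking$region_id[1]

  stim_aligned <- decode_stimulus_cv(ds, top_region, k = k, align = TRUE,
                                     seed = sub_seed(seed, 3L))
  stim_raw <- decode_stimulus_cv(ds, top_region, k = k, align = FALSE,
                                 seed = sub_seed(seed, 3L))
  fourclass <- combine_fourclass(sl, stim_aligned, ds)

  betas <- estimate_betas(ds, top_region)
  mwu <- compare_groups_mwu(betas)
  rsm <- build_rsm(betas)

  series <- region_mean_series(ds)
  graphs <- lapply(series, correlation_network, threshold = threshold)
  edges <- lapply(graphs, seed_edges, seed_region = top_region)

  summary <- list(
    top_region = top_region,
    top_region_inner_accuracy = sl$ranking$mean_acc[1],
    group_accuracy = sl$metrics$accuracy,
    group_accuracy_se = sl$metrics$accuracy_se,
    stimulus_accuracy_aligned = stim_aligned$metrics$accuracy,
    stimulus_accuracy_unaligned = stim_raw$metrics$accuracy,
    fourclass_balanced_accuracy = fourclass$balanced_accuracy,
    fourclass_anova_F = fourclass$anova$F,
    fourclass_anova_p = fourclass$anova$p,
    mwu_U = mwu$U,
    mwu_p = mwu$p_two_sided,
    seed_edge_counts = vapply(edges, nrow, integer(1)),
    seed = seed)

  out <- structure(list(dataset = ds, superlearner = sl,
                        stimulus_aligned = stim_aligned,
                        stimulus_unaligned = stim_raw,
                        fourclass = fourclass, betas = betas, mwu = mwu,
                        rsm = rsm, graphs = graphs, seed_edges = edges,
                        summary = summary, seed = seed),
                   class = "anx_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(x$superlearner$ranking),
                     file.path(out_dir, "region_ranking.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(x$superlearner$subject_predictions,
                     file.path(out_dir, "subject_predictions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (g in names(x$graphs)) {
    ed <- x$graphs[[g]]$edges
    if (nrow(ed)) ed <- cbind(group = g, ed)
    utils::write.table(ed, file.path(out_dir, sprintf("edges_%s.tsv", g)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(x$stimulus_aligned$class_precision_by_fold,
                   file.path(out_dir, "stimulus_precision_aligned.csv"))
  utils::write.csv(x$fourclass$class_precision_by_fold,
                   file.path(out_dir, "fourclass_precision.csv"))
  for (g in names(x$rsm))
    utils::write.csv(x$rsm[[g]], file.path(out_dir, sprintf("rsm_%s.csv", g)))
  jsonlite::write_json(x$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.anx_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<anx_pipeline>\n")
  cat(sprintf("  top region:               #%s (inner-CV accuracy %.1f%%)\n",
              s$top_region, 100 * s$top_region_inner_accuracy))
  cat(sprintf("  group accuracy:           %.1f%% (SE %.1f%%)\n",
              100 * s$group_accuracy, 100 * s$group_accuracy_se))
  cat(sprintf("  stimulus accuracy:        %.1f%% aligned / %.1f%% unaligned\n",
              100 * s$stimulus_accuracy_aligned,
              100 * s$stimulus_accuracy_unaligned))
  cat(sprintf("  four-class balanced acc.: %.1f%%\n",
              100 * s$fourclass_balanced_accuracy))
  cat(sprintf("  beta comparison:          U = %.1f, p = %.3g\n", s$mwu_U, s$mwu_p))
  cat(sprintf("  seed edges:               %s\n",
              paste(sprintf("%s %d", names(s$seed_edge_counts),
                            s$seed_edge_counts), collapse = ", ")))
  invisible(x)
}
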