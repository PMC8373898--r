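# The primary analysis: a super learner that treats atlas regions as a
# hyperparameter of the boosted logistic classifier, tuned by nested
# subject-level cross-validation, with per-subject majority voting and a
# region ranking.

#' Hyperparameter grid for the region super learner
#'
#' Defaults are the full study grid. `region_ids` defaults to every region in
#' the dataset; id 0 denotes the whole-brain pseudo-region (union of all
#' labeled voxels).
#'
#' @param n_estimators,learning_rate,max_iterations,penalty,C Candidate
#'   values for [adaboost_logistic()].
#' @param region_ids Candidate regions (NULL = all regions of the dataset).
#' @return An object of class `hyper_grid`.
#' @export
hyper_grid <- function(n_estimators = c(10, 50, 100, 150),
                       learning_rate = c(0.05, 1, 2),
                       max_iterations = c(100, 500, 1000),
                       penalty = c("l1", "l2", "none"),
                       C = c(0.5, 1, 2),
                       region_ids = NULL) {
  fields <- list(n_estimators = n_estimators, learning_rate = learning_rate,
                 max_iterations = max_iterations, penalty = penalty, C = C)
  for (nm in names(fields))
    if (length(fields[[nm]]) == 0) stop("empty grid field: ", nm, call. = FALSE)
  if (!all(penalty %in% c("l1", "l2", "none")))
    stop("penalty values must be l1, l2 or none", call. = FALSE)
  structure(c(fields, list(region_ids = region_ids)), class = "hyper_grid")
}

#' @export
print.hyper_grid <- function(x, ...) {
  sz <- prod(vapply(x[c("n_estimators", "learning_rate", "max_iterations",
                        "penalty", "C")], length, integer(1)))
  cat(sprintf("<hyper_grid> %d classifier configurations x %s regions\n", sz,
              if (is.null(x$region_ids)) "all" else length(x$region_ids)))
  invisible(x)
}

# Stratified subject folds: within each group, subjects are shuffled
# (seeded) and dealt round-robin, so outer folds stay balanced for
# diagnostic labels. Returns a named fold index per subject.
make_subject_folds <- function(subjects, groups, k, seed) {
  if (length(subjects) < k)
    stop("fewer subjects (", length(subjects), ") than folds (", k, ")",
         call. = FALSE)
  fold <- integer(length(subjects)); names(fold) <- subjects
  offset <- 0L
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    perm <- local_seed(sub_seed(seed, 7L + offset), sample(idx))
    fold[perm] <- ((seq_along(perm) - 1L + offset) %% k) + 1L
    offset <- offset + length(perm)
  }
  fold
}

# Stack one region's features over subjects once, so folds only index rows.
stack_region <- function(ds, region_id) {
  cols <- region_columns(ds, region_id)
  x <- do.call(rbind, lapply(ds$features, function(f) f[, cols, drop = FALSE]))
  x
}

# subject-level accuracy after majority voting test time points
vote_accuracy <- function(pred, subj_of_row, truth_by_subject) {
  votes <- vapply(split(pred, subj_of_row), majority_vote, character(1))
  mean(votes == truth_by_subject[names(votes)])
}

#' Nested cross-validated region search (super learner)
#'
#' For each outer fold (subjects split, stratified by group), an inner
#' subject-level cross-validation scores every (region, classifier
#' configuration) pair by mean subject-level accuracy after majority voting;
#' the winning configuration is refit on the full outer-training set and the
#' held-out subjects are predicted per time point, then majority-voted. Folds
#' always split subjects, never time points, so no subject's data straddles a
#' train/test boundary.
#'
#' Tie-breaking among equal-scoring configurations is deterministic: lowest
#' region id, then smallest `n_estimators`, then grid order.
#'
#' @param ds A `timepoint_dataset`.
#' @param grid A [hyper_grid()].
#' @param outer_k,inner_k Fold counts (study value 5 and 5).
#' @param seed Seed for the fold draws.
#' @param search `"joint"` tunes region x classifier grid jointly (the
#'   default); `"staged"` first ranks regions at the grid's first
#'   configuration, then tunes the classifier grid on the winning region only.
#' @param inner_metric Score used inside the inner CV: `"subject"`
#'   (majority-voted subject accuracy, the headline metric) or `"timepoint"`.
#' @return An object of class `region_sl` with the outer-CV results
#'   (`subject_predictions`, `timepoint_predictions`, `metrics`,
#'   `chosen`) and the `ranking` (class `region_ranking`).
#' @export
nested_region_search <- function(ds, grid = hyper_grid(), outer_k = 5,
                                 inner_k = 5, seed = 1,
                                 search = c("joint", "staged"),
                                 inner_metric = c("subject", "timepoint")) {
  search <- match.arg(search)
  inner_metric <- match.arg(inner_metric)
  subjects <- ds$subject_ids
  groups <- ds$group_labels[subjects]
  region_ids <- grid$region_ids %||% as.integer(names(ds$region_index))
  region_ids <- sort(as.integer(region_ids))
  for (r in region_ids) region_columns(ds, r)   # existence / nonzero check

  stacks <- lapply(region_ids, function(r) stack_region(ds, r))
  names(stacks) <- as.character(region_ids)
  n_t <- ds$T
  subj_of_row <- rep(subjects, each = n_t)
  row_group <- rep(groups, each = n_t)

  cfg <- expand.grid(region = region_ids, n_estimators = grid$n_estimators,
                     learning_rate = grid$learning_rate,
                     max_iterations = grid$max_iterations,
                     penalty = grid$penalty, C = grid$C,
                     stringsAsFactors = FALSE)
  cfg <- cfg[order(cfg$region, cfg$n_estimators, cfg$learning_rate,
                   cfg$max_iterations, cfg$penalty, cfg$C), , drop = FALSE]
  rownames(cfg) <- NULL

  fit_cfg <- function(co, rows) {
    adaboost_logistic(stacks[[as.character(co$region)]][rows, , drop = FALSE],
                      row_group[rows],
                      n_estimators = co$n_estimators,
                      learning_rate = co$learning_rate,
                      penalty = co$penalty, C = co$C,
                      max_iterations = co$max_iterations)
  }
  score_cfg <- function(co, train_rows, val_rows) {
    fit <- fit_cfg(co, train_rows)
    pred <- predict(fit, stacks[[as.character(co$region)]][val_rows, , drop = FALSE])
    if (inner_metric == "subject") {
      vote_accuracy(pred, subj_of_row[val_rows], groups)
    } else {
      mean(pred == row_group[val_rows])
    }
  }

  outer_fold <- make_subject_folds(subjects, groups, outer_k, sub_seed(seed, 1L))
  rank_acc <- matrix(NA_real_, nrow = length(region_ids), ncol = outer_k,
                     dimnames = list(as.character(region_ids), NULL))
  chosen <- list()
  subj_pred <- character(length(subjects)); names(subj_pred) <- subjects
  tp_pred <- vector("list", length(subjects)); names(tp_pred) <- subjects
  fold_acc <- numeric(outer_k)
  fold_metrics <- vector("list", outer_k)

  for (f in seq_len(outer_k)) {
    test_sub <- subjects[outer_fold == f]
    train_sub <- subjects[outer_fold != f]
    stopifnot(length(intersect(train_sub, test_sub)) == 0)
    inner_fold <- make_subject_folds(train_sub, groups[train_sub], inner_k,
                                     sub_seed(seed, 50L + f))
    inner_rows <- lapply(seq_len(inner_k), function(j) {
      val_sub <- train_sub[inner_fold == j]
      fit_sub <- setdiff(train_sub, val_sub)
      list(train = which(subj_of_row %in% fit_sub),
           val = which(subj_of_row %in% val_sub))
    })

    eval_rows <- function(rows_cfg) {
      vapply(seq_len(nrow(rows_cfg)), function(i) {
        co <- rows_cfg[i, , drop = FALSE]
        mean(vapply(inner_rows, function(ir) score_cfg(co, ir$train, ir$val),
                    numeric(1)))
      }, numeric(1))
    }

    if (search == "joint") {
      scores <- eval_rows(cfg)
      for (r in as.character(region_ids))
        rank_acc[r, f] <- max(scores[cfg$region == as.integer(r)])
      best <- cfg[which.max(scores), , drop = FALSE]
    } else {
      stage1 <- data.frame(region = region_ids,
                           n_estimators = grid$n_estimators[1],
                           learning_rate = grid$learning_rate[1],
                           max_iterations = grid$max_iterations[1],
                           penalty = grid$penalty[1], C = grid$C[1],
                           stringsAsFactors = FALSE)
      s1 <- eval_rows(stage1)
      rank_acc[, f] <- s1
      best_region <- region_ids[which.max(s1)]
      stage2 <- cfg[cfg$region == best_region, , drop = FALSE]
      s2 <- eval_rows(stage2)
      best <- stage2[which.max(s2), , drop = FALSE]
    }

    fit <- fit_cfg(best, which(subj_of_row %in% train_sub))
    test_rows <- which(subj_of_row %in% test_sub)
    pred <- predict(fit, stacks[[as.character(best$region)]][test_rows, , drop = FALSE])
    preds_by_sub <- split(pred, subj_of_row[test_rows])
    for (s in names(preds_by_sub)) {
      tp_pred[[s]] <- unname(preds_by_sub[[s]])
      subj_pred[s] <- majority_vote(preds_by_sub[[s]])
    }
    fold_metrics[[f]] <- classification_metrics(groups[test_sub], subj_pred[test_sub])
    fold_acc[f] <- fold_metrics[[f]]$accuracy
    chosen[[f]] <- cbind(fold = f, best)
  }

  overall <- classification_metrics(groups, subj_pred)
  metrics <- list(
    accuracy = overall$accuracy,
    accuracy_se = std_error(fold_acc),
    precision = overall$precision,
    recall = overall$recall,
    f1 = overall$f1,
    per_class = overall$per_class,
    per_fold_accuracy = fold_acc,
    precision_se = std_error(vapply(fold_metrics, `[[`, numeric(1), "precision")),
    recall_se = std_error(vapply(fold_metrics, `[[`, numeric(1), "recall")),
    f1_se = std_error(vapply(fold_metrics, `[[`, numeric(1), "f1")))

  ranking <- data.frame(
    region_id = region_ids,
    mean_acc = rowMeans(rank_acc),
    ste = apply(rank_acc, 1, std_error))
  nm <- ds$region_table$name[match(ranking$region_id, ds$region_table$region_id)]
  ranking$name <- ifelse(is.na(nm) & ranking$region_id == 0, "whole_brain", nm)
  ranking <- ranking[order(-ranking$mean_acc, ranking$region_id),
                     c("region_id", "name", "mean_acc", "ste")]
  rownames(ranking) <- NULL
  class(ranking) <- c("region_ranking", "data.frame")

  subject_predictions <- data.frame(
    subject = subjects,
    group = unname(groups),
    fold = unname(outer_fold[subjects]),
    predicted = unname(subj_pred[subjects]),
    timepoint_accuracy = vapply(subjects, function(s)
      mean(tp_pred[[s]] == groups[s]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(subject_predictions) <- NULL

  structure(list(ranking = ranking,
                 subject_predictions = subject_predictions,
                 timepoint_predictions = tp_pred,
                 metrics = metrics,
                 chosen = do.call(rbind, chosen),
                 outer_fold = outer_fold,
                 grid = grid, search = search, inner_metric = inner_metric,
                 seed = seed,
                 group_labels = groups),
            class = "region_sl")
}

#' @export
print.region_ranking <- function(x, ...) {
  cat("Region ranking (mean inner-CV accuracy +/- SE across outer folds):\n")
  print.data.frame(utils::head(x, 10), digits = 3)
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more regions\n", sep = "")
  invisible(x)
}

#' @export
print.region_sl <- function(x, ...) {
  cat(sprintf("<region_sl> %s search over %d regions, seed %d\n",
              x$search, nrow(x$ranking), x$seed))
  cat(sprintf("  subject accuracy %.1f%% (SE %.1f%%), macro precision %.1f%%, recall %.1f%%, F1 %.1f%%\n",
              100 * x$metrics$accuracy, 100 * x$metrics$accuracy_se,
              100 * x$metrics$precision, 100 * x$metrics$recall,
              100 * x$metrics$f1))
  cat(sprintf("  top region: %s (#%d), inner-CV accuracy %.1f%%\n",
              x$ranking$name[1], x$ranking$region_id[1],
              100 * x$ranking$mean_acc[1]))
  invisible(x)
}

#' @export
summary.region_sl <- function(object, ...) {
  print(object)
  cat("\nChosen configuration per outer fold:\n")
  print(object$chosen, row.names = FALSE)
  cat("\n")
  print(object$ranking)
  invisible(object)
}

#' Per-category accuracy with bootstrap confidence intervals
#'
#' Groups subjects by a covariate (age bin, scanner site, anxiety subtype...)
#' and reports each category's mean per-subject accuracy — the fraction of
#' that subject's time-point predictions that match the true group — with a
#' percentile-bootstrap confidence interval over subjects.
#'
#' @param result A [nested_region_search()] fit.
#' @param covariate Named vector mapping every subject to a category.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return Data frame: category, n, mean_accuracy, ci_lo, ci_hi.
#' @export
accuracy_by_covariate <- function(result, covariate, n_boot = 2000,
                                  conf = 0.95, seed = 1) {
  sp <- result$subject_predictions
  unknown <- setdiff(names(covariate), sp$subject)
  if (length(unknown))
    stop("covariate names unknown subjects: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(sp$subject, names(covariate))
  if (length(missing))
    stop("covariate undefined for subjects: ", paste(missing, collapse = ", "),
         call. = FALSE)
  acc <- sp$timepoint_accuracy; names(acc) <- sp$subject
  cats <- sort(unique(as.character(covariate)))
  alpha <- (1 - conf) / 2
  out <- lapply(cats, function(cl) {
    a <- acc[names(covariate)[covariate == cl]]
    bs <- local_seed(sub_seed(seed, match(cl, cats)), {
      vapply(seq_len(n_boot), function(i)
        mean(a[sample.int(length(a), replace = TRUE)]), numeric(1))
    })
    data.frame(category = cl, n = length(a), mean_accuracy = mean(a),
               ci_lo = unname(stats::quantile(bs, alpha)),
               ci_hi = unname(stats::quantile(bs, 1 - alpha)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
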