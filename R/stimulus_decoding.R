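# Decoding fearful vs angry time points in (optionally) SRM-aligned space,
# and the coupled four-class group x stimulus ensemble.

#' Cross-validated stimulus decoding in a region
#'
#' Folds split subjects (never time points). With `align = TRUE` a shared
#' response model is fit on the training subjects only, test subjects are
#' mapped in via [srm_new_subject()], and a linear max-margin classifier
#' (SVM, fixed cost) is trained on the aligned training time points; with
#' `align = FALSE` the classifier sees raw voxel features. There is no inner
#' CV and no majority vote: every labeled time point is predicted once and
#' metrics are averaged across folds.
#'
#' @param ds A `timepoint_dataset`.
#' @param region_id Region to decode from (0 = whole brain).
#' @param k Shared-space dimension when aligning.
#' @param folds Number of subject folds (study value 5).
#' @param align Use shared-response alignment?
#' @param cost Linear SVM cost (fixed, default 1; nothing is tuned here).
#' @param seed Seed for fold assignment and SRM initialization.
#' @param srm_method,srm_max_iter Passed to [srm()] when aligning.
#' @return An object of class `stimulus_cv`: per-time-point predictions,
#'   fold assignment, per-fold and pooled metrics, the per-fold per-class
#'   precision matrix, and (for the leakage audit) the subjects each fold's
#'   SRM was fit on.
#' @export
decode_stimulus_cv <- function(ds, region_id, k = 10, folds = 5, align = TRUE,
                               cost = 1, seed = 1,
                               srm_method = "deterministic",
                               srm_max_iter = 100) {
  cols <- region_columns(ds, region_id)
  v <- length(cols)
  if (align && k >= v)
    stop("k = ", k, " must be < the region's voxel count (", v, ")", call. = FALSE)
  conds <- sort(unique(ds$stimulus_labels))
  if (length(conds) < 2) stop("only one stimulus condition present", call. = FALSE)
  subjects <- ds$subject_ids
  groups <- ds$group_labels[subjects]
  fold <- make_subject_folds(subjects, groups, folds, sub_seed(seed, 11L))
  y <- factor(ds$stimulus_labels, levels = conds)

  preds <- vector("list", length(subjects)); names(preds) <- subjects
  fold_metrics <- vector("list", folds)
  srm_train_subjects <- vector("list", folds)

  for (f in seq_len(folds)) {
    test_sub <- subjects[fold == f]
    train_sub <- subjects[fold != f]
    stopifnot(length(intersect(train_sub, test_sub)) == 0)
    if (align) {
      xi <- lapply(train_sub, function(s) t(ds$features[[s]][, cols, drop = FALSE]))
      names(xi) <- train_sub
      space <- srm(xi, k = k, method = srm_method, max_iter = srm_max_iter,
                   seed = sub_seed(seed, 500L + f))
      srm_train_subjects[[f]] <- train_sub
      x_train <- do.call(rbind, lapply(train_sub, function(s)
        t(predict(space, xi[[s]], s))))
      x_test_list <- lapply(test_sub, function(s) {
        est <- srm_new_subject(space, t(ds$features[[s]][, cols, drop = FALSE]))
        t(est$shared)
      })
    } else {
      x_train <- do.call(rbind, lapply(train_sub, function(s)
        ds$features[[s]][, cols, drop = FALSE]))
      x_test_list <- lapply(test_sub, function(s)
        ds$features[[s]][, cols, drop = FALSE])
    }
    y_train <- rep(y, length(train_sub))
    fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = cost,
                      scale = FALSE)
    y_test <- character(0); p_test <- character(0)
    for (i in seq_along(test_sub)) {
      p <- as.character(predict(fit, x_test_list[[i]]))
      preds[[test_sub[i]]] <- p
      y_test <- c(y_test, as.character(y))
      p_test <- c(p_test, p)
    }
    fold_metrics[[f]] <- classification_metrics(y_test, p_test)
  }

  all_true <- rep(as.character(y), length(subjects))
  all_pred <- unlist(preds[subjects], use.names = FALSE)
  overall <- classification_metrics(all_true, all_pred)
  facc <- vapply(fold_metrics, `[[`, numeric(1), "accuracy")
  class_precision <- vapply(fold_metrics, function(m) {
    p <- m$per_class$precision[match(conds, m$per_class$class)]
    ifelse(is.na(p), 0, p)
  }, numeric(length(conds)))
  class_precision <- matrix(class_precision, nrow = length(conds),
                            dimnames = list(conds, paste0("fold", seq_len(folds))))

  structure(list(predictions = preds,
                 fold_assignment = fold,
                 conditions = conds,
                 aligned = align,
                 region_id = region_id, k = if (align) k else NA_integer_,
                 metrics = list(accuracy = overall$accuracy,
                                accuracy_se = std_error(facc),
                                precision = overall$precision,
                                recall = overall$recall,
                                f1 = overall$f1,
                                per_class = overall$per_class,
                                per_fold_accuracy = facc),
                 class_precision_by_fold = class_precision,
                 srm_train_subjects = srm_train_subjects,
                 stimulus_labels = as.character(y),
                 seed = seed),
            class = "stimulus_cv")
}

#' @export
print.stimulus_cv <- function(x, ...) {
  cat(sprintf("<stimulus_cv> region %s, %s, %d folds\n",
              x$region_id, if (x$aligned) sprintf("SRM-aligned (k = %d)", x$k)
              else "unaligned", ncol(x$class_precision_by_fold)))
  cat(sprintf("  time-point accuracy %.1f%% (SE %.1f%%), macro precision %.1f%%, F1 %.1f%%\n",
              100 * x$metrics$accuracy, 100 * x$metrics$accuracy_se,
              100 * x$metrics$precision, 100 * x$metrics$f1))
  invisible(x)
}

#' One-way ANOVA across per-fold class precisions
#'
#' Fixed-effects one-way ANOVA testing whether the four classes differ in
#' their fold-wise precision.
#'
#' @param per_fold_class_precisions Classes x folds numeric matrix.
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
precision_anova <- function(per_fold_class_precisions) {
  m <- as.matrix(per_fold_class_precisions)
  if (ncol(m) < 2) stop("need >= 2 folds", call. = FALSE)
  if (any(rowSums(is.finite(m)) < 2))
    stop("every class needs >= 2 finite values", call. = FALSE)
  d <- data.frame(value = as.vector(m),
                  class = factor(rep(rownames(m) %||% seq_len(nrow(m)),
                                     times = ncol(m))))
  class_means <- tapply(d$value, d$class, mean)
  ssb <- sum(tapply(d$value, d$class, length) * (class_means - mean(d$value))^2)
  ss_total <- sum((d$value - mean(d$value))^2)
  if (ssb <= 1e-12 * max(ss_total, mean(d$value)^2, .Machine$double.xmin)) {
    # all class means identical: no between-class variance to test
    return(list(F = 0, p = 1, df_between = nrow(m) - 1,
                df_within = length(d$value) - nrow(m)))
  }
  tab <- stats::anova(stats::lm(value ~ class, data = d))
  list(F = unname(tab$`F value`[1]), p = unname(tab$`Pr(>F)`[1]),
       df_between = tab$Df[1], df_within = tab$Df[2])
}

#' Couple group and stimulus predictions into the four-class ensemble
#'
#' Each time point's four-class prediction is its subject's predicted group
#' crossed with its predicted condition (e.g. `anxious_fear`); truth is built
#' the same way from the dataset. Balanced accuracy is the unweighted mean of
#' the four per-class recalls. Per-fold class precisions (folds inherited
#' from the stimulus model, since group predictions broadcast over a
#' subject's time points) feed the one-way ANOVA.
#'
#' @param group_preds Named vector mapping each subject to a predicted group,
#'   or a [nested_region_search()] fit.
#' @param stim_result A [decode_stimulus_cv()] fit.
#' @param ds The `timepoint_dataset` both models were run on.
#' @return An object of class `fourclass_result`.
#' @export
combine_fourclass <- function(group_preds, stim_result, ds) {
  if (inherits(group_preds, "region_sl")) {
    gp <- group_preds$subject_predictions$predicted
    names(gp) <- group_preds$subject_predictions$subject
    group_preds <- gp
  }
  subjects <- ds$subject_ids
  if (!setequal(names(group_preds), subjects))
    stop("group predictions do not cover the dataset's subjects", call. = FALSE)
  if (!setequal(names(stim_result$predictions), subjects))
    stop("stimulus predictions do not cover the dataset's subjects", call. = FALSE)

  t_n <- ds$T
  truth <- character(0); pred <- character(0); fold <- integer(0)
  for (s in subjects) {
    sp <- stim_result$predictions[[s]]
    if (length(sp) != t_n)
      stop("stimulus predictions for ", s, " cover ", length(sp),
           " time points, expected ", t_n, call. = FALSE)
    truth <- c(truth, paste(ds$group_labels[[s]], ds$stimulus_labels, sep = "_"))
    pred <- c(pred, paste(group_preds[[s]], sp, sep = "_"))
    fold <- c(fold, rep(stim_result$fold_assignment[[s]], t_n))
  }
  classes <- sort(unique(truth))
  overall <- classification_metrics(truth, pred)
  recalls <- overall$per_class$recall[match(classes, overall$per_class$class)]
  balanced <- mean(recalls)

  folds <- sort(unique(fold))
  class_precision <- vapply(folds, function(f) {
    m <- classification_metrics(truth[fold == f], pred[fold == f])
    p <- m$per_class$precision[match(classes, m$per_class$class)]
    ifelse(is.na(p), 0, p)
  }, numeric(length(classes)))
  class_precision <- matrix(class_precision, nrow = length(classes),
                            dimnames = list(classes, paste0("fold", folds)))
  aov_res <- precision_anova(class_precision)

  structure(list(truth = truth, predictions = pred, fold = fold,
                 classes = classes,
                 balanced_accuracy = balanced,
                 accuracy = overall$accuracy,
                 per_class = overall$per_class,
                 class_precision_by_fold = class_precision,
                 anova = aov_res),
            class = "fourclass_result")
}

#' @export
print.fourclass_result <- function(x, ...) {
  cat(sprintf("<fourclass_result> balanced accuracy %.1f%% over %d classes\n",
              100 * x$balanced_accuracy, length(x$classes)))
  print(x$per_class, row.names = FALSE, digits = 3)
  cat(sprintf("  precision ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  invisible(x)
}
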