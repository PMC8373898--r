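test_that("stimulus decoding respects label symmetry and subject folds", {
  co <- generate_cohort(tiny_spec(seed = 61))
  ds <- cohort_dataset(co)
  res <- decode_stimulus_cv(ds, 3, k = 2, folds = 4, align = TRUE, seed = 8)

  # every labeled time point predicted exactly once
  expect_equal(sort(names(res$predictions)), sort(ds$subject_ids))
  expect_true(all(vapply(res$predictions, length, integer(1)) == ds$T))
  # SRM never sees a test subject (leakage guard)
  for (f in seq_along(res$srm_train_subjects)) {
    test_sub <- names(res$fold_assignment)[res$fold_assignment == f]
    expect_length(intersect(res$srm_train_subjects[[f]], test_sub), 0)
  }

  # scoring the same predictions against inverted labels gives 1 - accuracy
  flipped <- ifelse(ds$stimulus_labels == "fear", "anger", "fear")
  all_pred <- unlist(res$predictions[ds$subject_ids], use.names = FALSE)
  inv <- classification_metrics(rep(flipped, length(ds$subject_ids)), all_pred)
  expect_equal(inv$accuracy, 1 - res$metrics$accuracy, tolerance = 1e-12)
  # relabeling the training conditions leaves the decoding problem unchanged
  ds_flip <- ds
  ds_flip$stimulus_labels <- flipped
  res_flip <- decode_stimulus_cv(ds_flip, 3, k = 2, folds = 4, align = TRUE, seed = 8)
  expect_equal(res_flip$metrics$accuracy, res$metrics$accuracy, tolerance = 1e-12)

  expect_error(decode_stimulus_cv(ds, 3, k = 50, align = TRUE), "voxel count")
})

test_that("alignment rescues cross-subject decoding on a planted cohort", {
  co <- generate_cohort(tiny_spec(seed = 71, n_anxious = 6, n_control = 6))
  ds <- cohort_dataset(co)
  aligned <- decode_stimulus_cv(ds, 3, k = 2, folds = 4, align = TRUE, seed = 2)
  raw <- decode_stimulus_cv(ds, 3, k = 2, folds = 4, align = FALSE, seed = 2)
  expect_gte(aligned$metrics$accuracy, 0.8)
  expect_lte(raw$metrics$accuracy, 0.65)
})

test_that("four-class coupling composes group and stimulus predictions", {
  co <- generate_cohort(tiny_spec(seed = 81))
  ds <- cohort_dataset(co)
  stim <- decode_stimulus_cv(ds, 3, k = 2, folds = 4, align = TRUE, seed = 3)

  # both sources perfect -> balanced accuracy 1
  perfect_groups <- ds$group_labels
  stim_perfect <- stim
  for (s in ds$subject_ids) stim_perfect$predictions[[s]] <- ds$stimulus_labels
  fc <- combine_fourclass(perfect_groups, stim_perfect, ds)
  expect_equal(fc$balanced_accuracy, 1)
  expect_equal(length(fc$classes), 4)

  # group perfect, stimulus at chance -> balanced accuracy ~ 0.5
  stim_chance <- stim
  set.seed(9)
  for (s in ds$subject_ids)
    stim_chance$predictions[[s]] <- sample(c("fear", "anger"), ds$T, replace = TRUE)
  fc2 <- combine_fourclass(perfect_groups, stim_chance, ds)
  expect_equal(fc2$balanced_accuracy, 0.5, tolerance = 0.08)

  # balanced accuracy equals the unweighted mean of per-class recalls
  fc3 <- combine_fourclass(perfect_groups, stim, ds)
  expect_equal(fc3$balanced_accuracy, mean(fc3$per_class$recall))

  bad <- perfect_groups[-1]
  expect_error(combine_fourclass(bad, stim, ds), "cover")
})

test_that("four-class majority baseline reproduces the 26% chance level", {
  # 23 control / 22 anxious subjects, conditions balanced within subject:
  # the largest class is control x one condition = 23/90 of time points
  groups <- rep(c("non_anxious", "anxious"), c(23, 22))
  truth <- as.vector(outer(c("fear", "anger"), groups,
                           function(cond, g) paste(g, cond, sep = "_")))
  base <- classification_metrics(truth, rep("non_anxious_fear", length(truth)))
  expect_equal(base$accuracy, 23 / 90)
  expect_equal(round(100 * base$accuracy), 26)
})

test_that("precision ANOVA matches the brute-force SS decomposition", {
  m <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(4, 5, 6))
  res <- precision_anova(m)
  expect_equal(res$F, 5)                        # between-SS 15/3, within-SS 8/8
  expect_equal(res$df_between, 3)
  expect_equal(res$df_within, 8)

  set.seed(12)
  for (i in 1:10) {
    m2 <- matrix(runif(20), 4, 5)
    expect_equal(precision_anova(m2)$F, bf_anova_f(m2), tolerance = 1e-10)
  }

  # identical precisions in every cell: no between-class variance
  res0 <- precision_anova(matrix(0.7, 4, 5))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  expect_error(precision_anova(matrix(1, 4, 1)), "folds")
})
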