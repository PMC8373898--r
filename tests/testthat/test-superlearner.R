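test_that("majority vote returns the modal label and rejects empty input", {
  expect_equal(majority_vote(rep(c("anxious", "non_anxious"), c(20, 15))), "anxious")
  expect_equal(majority_vote(rep("x", 35)), "x")
  expect_equal(majority_vote(rep(c("a", "b"), c(18, 17))), "a")
  expect_error(majority_vote(character(0)), "empty")
})

test_that("classification metrics reproduce hand-counted values", {
  # perfect predictions
  m <- classification_metrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # majority-class baseline on the study's 23 control / 22 anxious split
  truth <- rep(c("non_anxious", "anxious"), c(23, 22))
  base <- classification_metrics(truth, rep("non_anxious", 45))
  expect_equal(base$accuracy, 23 / 45)
  expect_equal(round(100 * base$accuracy, 1), 51.1)

  # 2x2 confusion with TP=3, FP=1, FN=2, TN=4 for the positive class
  truth2 <- rep(c("pos", "neg"), c(5, 5))
  pred2 <- c(rep("pos", 3), rep("neg", 2), rep("pos", 1), rep("neg", 4))
  m2 <- classification_metrics(truth2, pred2)
  pos <- m2$per_class[m2$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$recall, 0.6)

  expect_error(classification_metrics(c("a"), c("a", "b")), "differ")
  expect_error(classification_metrics(character(0), character(0)), "empty")
})

test_that("nested search recovers the planted region without leaking subjects", {
  co <- generate_cohort(tiny_spec(seed = 21))
  ds <- cohort_dataset(co)
  sl <- nested_region_search(ds, grid = reduced_grid(), outer_k = 4,
                             inner_k = 3, seed = 5)

  expect_equal(sl$ranking$region_id[1], 3)            # planted signal region
  expect_gte(sl$metrics$accuracy, 0.75)

  # every subject appears in exactly one outer test fold
  expect_equal(sort(names(sl$outer_fold)), sort(ds$subject_ids))
  expect_true(all(table(sl$subject_predictions$subject) == 1))

  # majority-vote subject accuracy >= mean time-point accuracy when
  # time-point accuracy is above chance
  tp_acc <- mean(sl$subject_predictions$timepoint_accuracy)
  if (tp_acc > 0.5) expect_gte(sl$metrics$accuracy, tp_acc - 0.1)

  # single-region grid trivially selects that region
  sl1 <- nested_region_search(ds, grid = reduced_grid(region_ids = 2),
                              outer_k = 4, inner_k = 3, seed = 5)
  expect_equal(unique(sl1$chosen$region), 2)

  expect_error(nested_region_search(ds, grid = reduced_grid(region_ids = 99),
                                    outer_k = 4, inner_k = 3), "not present")
  expect_error(nested_region_search(ds, grid = reduced_grid(), outer_k = 20),
               "fewer subjects")
})

test_that("region ranking is equivariant under region relabeling", {
  co <- generate_cohort(tiny_spec(seed = 31))
  ds <- cohort_dataset(co)
  sl <- nested_region_search(ds, grid = reduced_grid(), outer_k = 4,
                             inner_k = 3, seed = 9)

  # relabel regions 1..4 -> 4..1 by renaming the region index
  ds2 <- ds
  relabel <- c("1" = "4", "2" = "3", "3" = "2", "4" = "1")
  names(ds2$region_index) <- unname(relabel[names(ds$region_index)])
  ds2$region_index <- ds2$region_index[order(as.integer(names(ds2$region_index)))]
  ds2$voxel_region <- as.integer(relabel[as.character(ds$voxel_region)])
  ds2$region_table$region_id <- as.integer(relabel[as.character(ds$region_table$region_id)])
  sl2 <- nested_region_search(ds2, grid = reduced_grid(), outer_k = 4,
                              inner_k = 3, seed = 9)

  r1 <- sl$ranking; r2 <- sl2$ranking
  r1$region_id <- as.integer(relabel[as.character(r1$region_id)])
  expect_equal(r2$mean_acc[order(r2$region_id)], r1$mean_acc[order(r1$region_id)])
  expect_equal(as.integer(relabel[as.character(sl$ranking$region_id[1])]),
               sl2$ranking$region_id[1])
})

test_that("whole-brain pseudo-region underperforms the planted region", {
  co <- generate_cohort(tiny_spec(seed = 41, n_anxious = 5, n_control = 5))
  ds <- cohort_dataset(co)
  sl <- nested_region_search(ds, grid = reduced_grid(region_ids = c(0, 3)),
                             outer_k = 4, inner_k = 3, seed = 3)
  rk <- sl$ranking
  expect_gte(rk$mean_acc[rk$region_id == 3], rk$mean_acc[rk$region_id == 0])
})

test_that("per-covariate accuracies come with percentile bootstrap CIs", {
  co <- generate_cohort(tiny_spec(seed = 51))
  ds <- cohort_dataset(co)
  sl <- nested_region_search(ds, grid = reduced_grid(region_ids = 3),
                             outer_k = 4, inner_k = 3, seed = 2)

  # perfectly predicted subjects give degenerate CIs at 100%
  sl_perfect <- sl
  sl_perfect$subject_predictions$timepoint_accuracy <- 1
  cov_all <- setNames(rep("site0", 8), ds$subject_ids)
  out <- accuracy_by_covariate(sl_perfect, cov_all, n_boot = 200)
  expect_equal(out$mean_accuracy, 1)
  expect_equal(out$ci_lo, 1); expect_equal(out$ci_hi, 1)

  # a single-subject category with 21/35 correct time points reports 60%
  sl_one <- sl
  sl_one$subject_predictions$timepoint_accuracy[1] <- 21 / 35
  cov_one <- setNames(c("solo", rep("rest", 7)), ds$subject_ids)
  out2 <- accuracy_by_covariate(sl_one, cov_one, n_boot = 200)
  expect_equal(out2$mean_accuracy[out2$category == "solo"], 0.6)

  # the bootstrap CI contains the point estimate
  cov_half <- setNames(rep(c("a", "b"), 4), ds$subject_ids)
  out3 <- accuracy_by_covariate(sl, cov_half, n_boot = 500, seed = 4)
  expect_true(all(out3$ci_lo <= out3$mean_accuracy + 1e-12))
  expect_true(all(out3$ci_hi >= out3$mean_accuracy - 1e-12))

  expect_error(accuracy_by_covariate(sl, cov_half[-1]), "undefined")
  expect_error(accuracy_by_covariate(sl, c(cov_half, ghost = "a")), "unknown")
})
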