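make_beta_ds <- function(t_n = 12, v = 6, n_sub = 4, signal = NULL, seed = 1) {
  # minimal timepoint_dataset-shaped object for regression tests
  set.seed(seed)
  labels <- rep(c("fear", "anger"), length.out = t_n)
  subs <- sprintf("s%02d", seq_len(n_sub))
  features <- lapply(subs, function(s) {
    x <- matrix(rnorm(t_n * v, sd = 0.0), t_n, v)
    if (!is.null(signal)) {
      x[labels == "fear", ] <- signal[1]
      x[labels == "anger", ] <- signal[2]
    }
    x
  })
  names(features) <- subs
  structure(list(features = features, stimulus_labels = labels,
                 group_labels = setNames(rep(c("anxious", "non_anxious"),
                                             length.out = n_sub), subs),
                 subject_ids = subs,
                 region_index = list("1" = seq_len(v)),
                 region_table = data.frame(region_id = 1, name = "r1",
                                           x = 0, y = 0, z = 0),
                 voxel_region = rep(1L, v), T = t_n, V = v),
            class = "timepoint_dataset")
}

test_that("noiseless condition betas are exact and linear in the data", {
  ds <- make_beta_ds(signal = c(2, 5))
  b <- estimate_betas(ds, 1)
  for (s in ds$subject_ids) {
    expect_equal(unname(b$betas[[s]]["fear", ]), rep(2, 6))
    expect_equal(unname(b$betas[[s]]["anger", ]), rep(5, 6))
  }
  # doubling the data doubles the betas
  ds2 <- ds
  ds2$features <- lapply(ds$features, function(m) 2 * m)
  b2 <- estimate_betas(ds2, 1)
  expect_equal(b2$betas[["s01"]], 2 * b$betas[["s01"]])

  # a single-condition design is rank-deficient
  ds_bad <- ds
  ds_bad$stimulus_labels <- rep("fear", ds$T)
  expect_error(estimate_betas(ds_bad, 1), "rank-deficient")
})

test_that("pure-noise betas scatter around zero at the expected scale", {
  set.seed(3)
  t_n <- 40; v <- 200
  labels <- rep(c("fear", "anger"), each = t_n / 2)
  x <- matrix(rnorm(t_n * v), t_n, v)
  ds <- make_beta_ds(t_n = t_n, v = v, n_sub = 1)
  ds$stimulus_labels <- labels
  ds$features[[1]] <- x
  b <- estimate_betas(ds, 1)$betas[[1]]
  se <- 1 / sqrt(t_n / 2)          # SE of a mean of T/2 unit-variance draws
  expect_lt(max(abs(b)), 5 * se)   # no systematic bias
  expect_equal(mean(abs(b) < 3 * se), 1, tolerance = 0.02)
})

test_that("Mann-Whitney U matches brute-force pair counting exactly", {
  set.seed(4)
  for (i in 1:200) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    # mix continuous and tied integer draws
    x <- if (i %% 2) rnorm(n1) else sample(0:5, n1, replace = TRUE)
    y <- if (i %% 2) rnorm(n2) else sample(0:5, n2, replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$U, bf_u(x, y))
    # antisymmetry with ties included
    expect_equal(res$U + mann_whitney_u(y, x)$U, n1 * n2)
  }
})

test_that("exact and approximate Mann-Whitney p-values agree for small n", {
  # frozen example: x < y entirely, n = 3 each -> U = 0, exact p = 2/20
  res <- mann_whitney_u(1:3, 4:6)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")

  # identical multisets give the tie midpoint U = n^2/2
  res_tie <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res_tie$U, 4.5)

  # normal approximation within 0.01 of the exact p for n1, n2 <= 12
  set.seed(5)
  for (i in 1:50) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    pe <- mann_whitney_u(x, y, exact = TRUE)$p
    pa <- mann_whitney_u(x, y, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.01)
    # cross-check the exact path against the base wilcox oracle
    w <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mann_whitney_u(x, y)$U, unname(w$statistic))
    expect_equal(pe, w$p.value, tolerance = 1e-12)
  }

  expect_warning(res_flat <- mann_whitney_u(rep(1, 4), rep(1, 5)), "tied")
  expect_equal(res_flat$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("group comparison pools per-voxel mean betas by group", {
  co <- generate_cohort(tiny_spec(seed = 91))
  ds <- cohort_dataset(co)
  b <- estimate_betas(ds, 3)
  cmp <- compare_groups_mwu(b)
  v <- length(ds$region_index[["3"]])
  expect_equal(cmp$n1, v); expect_equal(cmp$n2, v)
  expect_gte(cmp$U, 0); expect_lte(cmp$U, cmp$n1 * cmp$n2)
  expect_gt(cmp$p_two_sided, 0); expect_lte(cmp$p_two_sided, 1)
  expect_equal(cmp$orientation, "anxious")
  # the planted anxious shift makes anxious mean betas larger
  expect_gt(mean(cmp$group_means$anxious), mean(cmp$group_means$non_anxious))
})

test_that("representational dissimilarity matrices behave at the extremes", {
  ds <- make_beta_ds(v = 8)
  pat <- rnorm(8)
  for (s in ds$subject_ids) {
    ds$features[[s]][ds$stimulus_labels == "fear", ] <-
      matrix(pat, sum(ds$stimulus_labels == "fear"), 8, byrow = TRUE)
    ds$features[[s]][ds$stimulus_labels == "anger", ] <-
      matrix(pat, sum(ds$stimulus_labels == "anger"), 8, byrow = TRUE)
  }
  b <- estimate_betas(ds, 1)
  rsm <- build_rsm(b)
  for (g in names(rsm)) {
    expect_equal(diag(rsm[[g]]), c(fear = 0, anger = 0))
    expect_equal(rsm[[g]]["fear", "anger"], 0, tolerance = 1e-12)
  }

  # anti-correlated patterns give dissimilarity 2
  for (s in ds$subject_ids)
    ds$features[[s]][ds$stimulus_labels == "anger", ] <-
      matrix(-pat, sum(ds$stimulus_labels == "anger"), 8, byrow = TRUE)
  b2 <- estimate_betas(ds, 1)
  rsm2 <- build_rsm(b2)
  expect_equal(rsm2[["anxious"]]["fear", "anger"], 2, tolerance = 1e-12)

  # planted distinct condition patterns separate in the planted direction
  co <- generate_cohort(tiny_spec(seed = 101))
  dsc <- cohort_dataset(co)
  rsm3 <- build_rsm(estimate_betas(dsc, 3))
  expect_gt(rsm3[["anxious"]]["fear", "anger"], 0.1)
})
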