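# Fixtures are generated in code; nothing on disk.

# desk-scale cohort for unit tests: 8 subjects, 4 regions x 12 voxels
tiny_spec <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_anxious = 4, n_control = 4, atlas_shape = c(6, 6, 5),
         n_regions = 4, voxels_per_region = 12, signal_region_id = 3,
         k_shared = 2, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

# one boosted-logistic configuration; the region stays the searched
# hyperparameter
reduced_grid <- function(region_ids = NULL) {
  hyper_grid(n_estimators = 10, learning_rate = 1, max_iterations = 100,
             penalty = "l2", C = 1, region_ids = region_ids)
}

# brute-force Mann-Whitney U by explicit pair counting
bf_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

# brute-force one-way ANOVA F from the sum-of-squares decomposition
bf_anova_f <- function(mat) {
  v <- as.vector(mat); g <- rep(seq_len(nrow(mat)), times = ncol(mat))
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  dfb <- nrow(mat) - 1; dfw <- length(v) - nrow(mat)
  (ssb / dfb) / (ssw / dfw)
}
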