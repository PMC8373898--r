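# Condition activation patterns (betas) per subject by regression on the
# condition design, group comparison of the beta distributions by a two-tailed
# Mann-Whitney U test, and representational (dis)similarity matrices.

#' Estimate per-condition activation betas in a region
#'
#' Per subject and voxel, the least-squares solution of the time-point
#' features on fear/anger indicator regressors (optionally ridge-stabilized).
#' Every time point belongs to exactly one condition, so the design is
#' orthogonal and the betas equal the per-condition voxel means when
#' `ridge = 0`.
#'
#' @param ds A `timepoint_dataset`.
#' @param region_id Region to analyze (0 = whole brain).
#' @param ridge Optional ridge penalty added to the normal equations
#'   (default 0 = ordinary least squares).
#' @return An object of class `beta_maps`: per-subject condition x voxel
#'   coefficient matrices, the design, per-voxel residual variances, and the
#'   subjects' group labels.
#' @export
estimate_betas <- function(ds, region_id, ridge = 0) {
  cols <- region_columns(ds, region_id)
  conds <- TASK_CONDITIONS
  design <- vapply(conds, function(cl) as.numeric(ds$stimulus_labels == cl),
                   numeric(ds$T))
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient design: both conditions must be present", call. = FALSE)
  xtx <- crossprod(design) + ridge * diag(ncol(design))
  betas <- lapply(ds$subject_ids, function(s) {
    yy <- ds$features[[s]][, cols, drop = FALSE]
    b <- solve(xtx, crossprod(design, yy))
    rownames(b) <- conds
    b
  })
  names(betas) <- ds$subject_ids
  resid_var <- lapply(ds$subject_ids, function(s) {
    yy <- ds$features[[s]][, cols, drop = FALSE]
    res <- yy - design %*% betas[[s]]
    colSums(res^2) / max(ds$T - ncol(design), 1)
  })
  names(resid_var) <- ds$subject_ids
  structure(list(betas = betas, design = design, conditions = conds,
                 region_id = region_id, resid_var = resid_var,
                 subject_ids = ds$subject_ids,
                 groups = ds$group_labels[ds$subject_ids],
                 ridge = ridge),
            class = "beta_maps")
}

#' @export
print.beta_maps <- function(x, ...) {
  cat(sprintf("<beta_maps> region %s: %d subjects x %d conditions x %d voxels (ridge %.3g)\n",
              x$region_id, length(x$betas), length(x$conditions),
              ncol(x$betas[[1]]), x$ridge))
  invisible(x)
}

#' Write beta maps back into atlas space as NIfTI volumes
#'
#' One 3D volume per subject and condition, with the region's beta values at
#' its atlas voxels and zero elsewhere.
#'
#' @param betas An [estimate_betas()] result.
#' @param atlas The [atlas_parcellation()] the dataset was built from.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_beta_maps <- function(betas, atlas, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lab <- as.integer(atlas$labels)
  idx <- if (identical(as.integer(betas$region_id), 0L)) which(lab > 0)
         else which(lab == betas$region_id)
  for (s in names(betas$betas)) {
    for (cond in betas$conditions) {
      vol <- numeric(length(lab))
      vol[idx] <- betas$betas[[s]][cond, ]
      RNifti::writeNifti(RNifti::asNifti(array(vol, dim(atlas$labels))),
                         file.path(out_dir, sprintf("%s_%s_beta.nii.gz", s, cond)))
    }
  }
  invisible(out_dir)
}

#' Mann-Whitney U test (two-tailed)
#'
#' U is reported for the first sample: `U = #{(a, b): a > b} + ties/2` over
#' all pairs. The two-sided p-value uses the exact null distribution of U
#' when the pooled sample is tie-free and `n1 * n2` is small enough, full
#' enumeration of group assignments for small tied samples, and otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (group 1 and group 2).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` decides automatically.
#' @return List with `U`, `p`, `n1`, `n2` and the `method` used.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  assert_finite(c(x, y), "samples")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0

  if (all(duplicated(pooled)[-1])) {    # every value identical
    warning("all values tied; p = 1", call. = FALSE)
    return(list(U = u, p = 1, n1 = n1, n2 = n2, method = "degenerate"))
  }

  want_exact <- exact %||% (n1 * n2 <= 10000)
  method <- "normal_approx"
  p <- NULL
  if (want_exact && !has_ties) {
    p_lo <- stats::pwilcox(u, n1, n2)
    p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else if (want_exact && has_ties && choose(n1 + n2, n1) <= 2e5) {
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    p_lo <- mean(u_all <= u + 1e-9)
    p_hi <- mean(u_all >= u - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact_enumeration"
  }
  if (is.null(p)) {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (nn * (nn - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nn + 1 - tie_term))
    if (!has_ties) {
      # Edgeworth-corrected tail with the exact excess kurtosis of U,
      # gamma2 = -(6/5)(n1^2+n2^2+n1 n2+n1+n2) / (n1 n2 (N+1)); keeps the
      # approximation within 0.01 of the exact p down to very small samples
      g2 <- -(6 / 5) * (n1^2 + n2^2 + n1 * n2 + n1 + n2) / (n1 * n2 * (nn + 1))
      tail_le <- function(q) {    # P(U <= q) with continuity correction
        z <- (q + 0.5 - mu) / sigma
        min(1, max(0, stats::pnorm(z) - g2 / 24 * (z^3 - 3 * z) * stats::dnorm(z)))
      }
      p_lo <- tail_le(u)
      p_hi <- 1 - tail_le(u - 1)
      p <- min(1, 2 * min(p_lo, p_hi))
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  p <- max(p, 1e-300)   # p is in (0, 1]; guard double underflow at extreme U
  list(U = u, p = p, n1 = n1, n2 = n2, method = method)
}

#' Compare group beta distributions with a Mann-Whitney U test
#'
#' Pools each group's per-voxel mean betas (averaged over the group's
#' subjects and over conditions) and compares the two per-voxel samples with
#' a two-tailed Mann-Whitney U test, U reported for the first group
#' (anxious by default).
#'
#' @param betas An [estimate_betas()] result.
#' @param groups Optional named group labels (defaults to those recorded in
#'   `betas`).
#' @param orientation Group whose U is reported first.
#' @return An object of class `group_mwu`: `U`, `p_two_sided`, `n1`, `n2`,
#'   the per-group mean-beta vectors and the p-value method.
#' @export
compare_groups_mwu <- function(betas, groups = NULL, orientation = "anxious") {
  groups <- groups %||% betas$groups
  groups <- groups[names(betas$betas)]
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2) stop("need exactly two non-empty groups", call. = FALSE)
  if (!(orientation %in% lv))
    stop("orientation group '", orientation, "' not present", call. = FALSE)
  g1 <- orientation; g2 <- setdiff(lv, g1)
  mean_beta <- function(g) {
    subs <- names(groups)[groups == g]
    m <- Reduce(`+`, betas$betas[subs]) / length(subs)   # conditions x voxels
    colMeans(m)
  }
  v1 <- mean_beta(g1); v2 <- mean_beta(g2)
  res <- mann_whitney_u(v1, v2)
  structure(list(U = res$U, p_two_sided = res$p, n1 = res$n1, n2 = res$n2,
                 method = res$method,
                 group_means = stats::setNames(list(v1, v2), c(g1, g2)),
                 orientation = g1),
            class = "group_mwu")
}

#' @export
print.group_mwu <- function(x, ...) {
  cat(sprintf("<group_mwu> U = %.2f (%s first), n1 = %d, n2 = %d, two-sided p = %.4g (%s)\n",
              x$U, x$orientation, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Representational (dis)similarity matrices per group
#'
#' For each group, condition beta patterns are averaged across the group's
#' subjects and compared as `1 - Pearson r`, giving a symmetric
#' condition x condition matrix with zero diagonal. Zero-variance patterns
#' yield NA entries and a warning.
#'
#' @param betas An [estimate_betas()] result.
#' @param groups Optional named group labels.
#' @param metric Only `"pearson_dissimilarity"` is implemented.
#' @return Named list of condition x condition matrices, one per group.
#' @export
build_rsm <- function(betas, groups = NULL, metric = "pearson_dissimilarity") {
  metric <- match.arg(metric)
  groups <- groups %||% betas$groups
  groups <- groups[names(betas$betas)]
  conds <- betas$conditions
  if (length(conds) < 2) stop("need >= 2 conditions", call. = FALSE)
  out <- lapply(sort(unique(as.character(groups))), function(g) {
    subs <- names(groups)[groups == g]
    m <- Reduce(`+`, betas$betas[subs]) / length(subs)
    rsm <- matrix(0, length(conds), length(conds), dimnames = list(conds, conds))
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (i == j) next
      a <- m[conds[i], ]; b <- m[conds[j], ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("zero-variance pattern in group ", g, "; dissimilarity undefined",
                call. = FALSE)
        rsm[i, j] <- NA_real_
      } else {
        rsm[i, j] <- 1 - stats::cor(a, b)
      }
    }
    rsm
  })
  names(out) <- sort(unique(as.character(groups)))
  out
}
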