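# Shared response model: functional alignment of subjects' voxel patterns
# into a common k-dimensional space. X_i (V_i x T) ~ W_i S with orthonormal
# subject maps W_i and a shared response S (k x T). Two engines share one
# contract: a deterministic alternating orthogonal-Procrustes minimizer of
# sum_i ||X_i - W_i S||_F^2, and a probabilistic EM variant with a shared
# response covariance and per-subject isotropic noise.

procrustes_map <- function(a) {
  sv <- svd(a)
  sv$u %*% t(sv$v)
}

srm_objective <- function(x, w, s) {
  sum(vapply(seq_along(x), function(i) sum((x[[i]] - w[[i]] %*% s)^2), numeric(1)))
}

#' Fit a shared response model
#'
#' Data are column-centered per voxel over the training time points (centers
#' are stored and reapplied at transform time). Initialization is a seeded
#' random orthonormal map per subject.
#'
#' The deterministic engine alternates `S <- mean_i W_i' X_i` with the
#' orthogonal-Procrustes update `W_i <- UV'` from the SVD of `X_i S'`; its
#' `objective_trace` records the Frobenius objective, which is non-increasing
#' by construction. The probabilistic engine runs EM on the model
#' `x_t = W_i s_t + e`, `s_t ~ N(0, Sigma_s)`, `e ~ N(0, sigma2_i I)`; its
#' `objective_trace` records the negative log-likelihood (non-increasing by
#' EM theory) and `noise_vars` reports the per-subject noise variances.
#'
#' @param x List of V_i x T matrices (voxels x time points), optionally named
#'   by subject id.
#' @param k Shared-space dimension; must be < min(V_i).
#' @param method `"deterministic"` (default) or `"probabilistic"`.
#' @param max_iter,tol Convergence controls (relative objective change).
#' @param seed Seed for the random orthonormal initialization.
#' @return An object of class `srm`: per-subject maps `W` (orthonormal
#'   columns), shared response `S` (k x T), voxel centers `mu`,
#'   `objective_trace`, `converged`, and for the probabilistic engine
#'   `noise_vars` and `Sigma_s`.
#' @export
srm <- function(x, k, method = c("deterministic", "probabilistic"),
                max_iter = 200, tol = 1e-6, seed = 1) {
  method <- match.arg(method)
  if (!is.list(x) || length(x) == 0) stop("x must be a non-empty list", call. = FALSE)
  x <- lapply(x, as.matrix)
  for (i in seq_along(x)) assert_finite(x[[i]], sprintf("subject %d data", i))
  tt <- unique(vapply(x, ncol, integer(1)))
  if (length(tt) != 1) stop("all subjects must share T (columns)", call. = FALSE)
  vs <- vapply(x, nrow, integer(1))
  if (k > min(vs))
    stop("k = ", k, " must not exceed the smallest voxel count (", min(vs), ")",
         call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- length(x)
  subjects <- names(x) %||% as.character(seq_len(n))
  mu <- lapply(x, rowMeans)
  xc <- Map(function(m, c) m - c, x, mu)

  w <- lapply(seq_len(n), function(i) {
    local_seed(sub_seed(seed, 300L + i), random_orthonormal(vs[i], k))
  })

  if (method == "deterministic") {
    trace <- numeric(0); converged <- FALSE
    s <- NULL
    for (it in seq_len(max_iter)) {
      s <- Reduce(`+`, Map(function(wi, xi) crossprod(wi, xi), w, xc)) / n
      w <- Map(function(xi) procrustes_map(xi %*% t(s)), xc)
      obj <- srm_objective(xc, w, s)
      trace <- c(trace, obj)
      if (it > 1 && abs(trace[it - 1] - obj) <= tol * max(trace[1], 1e-12)) {
        converged <- TRUE
        break
      }
    }
    # final S consistent with the last W update
    s <- Reduce(`+`, Map(function(wi, xi) crossprod(wi, xi), w, xc)) / n
    out <- list(k = k, W = w, S = s, mu = mu, objective_trace = trace,
                converged = converged, method = method, subjects = subjects,
                T = tt, iterations = length(trace))
  } else {
    sigma2 <- vapply(xc, function(m) mean(m^2), numeric(1))
    sigma2 <- pmax(sigma2, 1e-8)
    sigma_s <- diag(k)
    trace <- numeric(0); converged <- FALSE
    es <- NULL
    for (it in seq_len(max_iter)) {
      # E-step (W_i' W_i = I makes the posterior covariance shared over t)
      cc <- sum(1 / sigma2)
      vs_post <- solve(solve(sigma_s) + cc * diag(k))
      proj <- Reduce(`+`, Map(function(wi, xi, s2) crossprod(wi, xi) / s2,
                              w, xc, as.list(sigma2)))
      es <- vs_post %*% proj                               # k x T posterior mean
      # M-step
      w <- Map(function(xi) procrustes_map(xi %*% t(es)), xc)
      sigma2 <- vapply(seq_len(n), function(i) {
        rss <- sum(xc[[i]]^2) - 2 * sum(diag(es %*% t(crossprod(w[[i]], xc[[i]])))) +
          sum(es^2) + tt * sum(diag(vs_post))
        max(rss / (tt * vs[i]), 1e-10)
      }, numeric(1))
      sigma_s <- vs_post + tcrossprod(es) / tt
      sigma_s <- (sigma_s + t(sigma_s)) / 2
      # observed-data negative log-likelihood via the determinant lemma
      cc <- sum(1 / sigma2)
      a <- solve(sigma_s) + cc * diag(k)
      logdet <- sum(vs * log(sigma2)) +
        determinant(a, logarithm = TRUE)$modulus +
        determinant(sigma_s, logarithm = TRUE)$modulus
      wx <- Reduce(`+`, Map(function(wi, xi, s2) crossprod(wi, xi) / s2,
                            w, xc, as.list(sigma2)))
      quad <- sum(vapply(seq_len(n), function(i) sum(xc[[i]]^2) / sigma2[i],
                         numeric(1))) -
        sum(wx * solve(a, wx))
      nll <- 0.5 * (tt * (sum(vs) * log(2 * pi) + as.numeric(logdet)) + quad)
      trace <- c(trace, nll)
      if (it > 1 && abs(trace[it - 1] - nll) <= tol * max(abs(trace[1]), 1e-12)) {
        converged <- TRUE
        break
      }
    }
    out <- list(k = k, W = w, S = es, mu = mu, objective_trace = trace,
                converged = converged, method = method,
                noise_vars = sigma2, Sigma_s = sigma_s, subjects = subjects,
                T = tt, iterations = length(trace))
  }
  names(out$W) <- subjects
  names(out$mu) <- subjects
  structure(out, class = "srm")
}

#' @export
print.srm <- function(x, ...) {
  cat(sprintf("<srm> %s, %d subjects, k = %d, T = %d, %d iterations (%s)\n",
              x$method, length(x$W), x$k, x$T, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  cat(sprintf("  final objective %.6g\n", utils::tail(x$objective_trace, 1)))
  invisible(x)
}

# resolve a subject argument (id or index) to an index
srm_subject_index <- function(object, subject) {
  if (is.character(subject)) {
    i <- match(subject, object$subjects)
    if (is.na(i)) stop("unknown subject: ", subject, call. = FALSE)
  } else {
    i <- as.integer(subject)
    if (i < 1 || i > length(object$W)) stop("subject index out of range", call. = FALSE)
  }
  i
}

#' Project new data of a fitted subject into the shared space
#'
#' Applies the training centering and the subject's orthonormal map:
#' `W_i' (X - mu_i)`.
#'
#' @param object A fitted [srm()].
#' @param newdata V_i x T' matrix for that subject.
#' @param subject Subject id (character) or index.
#' @param ... Unused.
#' @return A k x T' matrix of shared-space responses.
#' @export
predict.srm <- function(object, newdata, subject, ...) {
  i <- srm_subject_index(object, subject)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) != nrow(object$W[[i]]))
    stop("voxel count mismatch: expected ", nrow(object$W[[i]]),
         ", got ", nrow(newdata), call. = FALSE)
  crossprod(object$W[[i]], newdata - object$mu[[i]])
}

#' Estimate an orthonormal map for a held-out subject
#'
#' Solves the orthogonal Procrustes problem `min ||X - W S||_F` over
#' orthonormal `W` for a subject that was not in the training set, without
#' refitting the shared response.
#'
#' @param space A fitted [srm()].
#' @param x_new V x T matrix; T must match the training T.
#' @return List with the orthonormal map `W` (V x k), the voxel centers
#'   `center`, and `shared` = `W'(X - center)`, the new subject's
#'   shared-space responses.
#' @export
srm_new_subject <- function(space, x_new) {
  x_new <- as.matrix(x_new)
  assert_finite(x_new, "new subject data")
  if (ncol(x_new) != ncol(space$S))
    stop("time-point count mismatch: expected ", ncol(space$S),
         ", got ", ncol(x_new), call. = FALSE)
  mu <- rowMeans(x_new)
  xc <- x_new - mu
  a <- xc %*% t(space$S)
  sv <- svd(a)
  if (min(sv$d) <= 1e-10 * max(sv$d, 1e-300))
    stop("degenerate cross-product (rank < k); lower k or supply more time points",
         call. = FALSE)
  w <- sv$u %*% t(sv$v)
  list(W = w, center = mu, shared = crossprod(w, xc))
}
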