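# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package internals do
#' not perturb user scripts.
#' @noRd
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic seed-derivation scheme: every stochastic sub-step of a seeded
# operation draws from sub_seed(root, stream) with a documented stream id, so
# partial regeneration (e.g. one subject's run) is stable. Result stays within
# 32-bit integer range.
sub_seed <- function(root, stream) {
  as.integer((as.numeric(root) %% 65011 + 1) * 9973 + as.numeric(stream) * 7919) %% 2147483629L
}

# Random matrix with orthonormal columns (QR of a Gaussian matrix, signs fixed
# so the draw is a deterministic function of the RNG stream).
random_orthonormal <- function(v, k) {
  stopifnot(k <= v)
  m <- matrix(stats::rnorm(v * k), v, k)
  qr_m <- qr(m)
  q <- qr.Q(qr_m)
  d <- sign(diag(qr.R(qr_m)))
  d[d == 0] <- 1
  sweep(q, 2, d, `*`)
}

# z-score columns; zero-variance columns become exact zeros rather than NaN so
# masks containing dead voxels survive standardization.
zscore_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  x <- sweep(x, 2, mu, `-`)
  pos <- sdv > 0
  x[, pos] <- sweep(x[, pos, drop = FALSE], 2, sdv[pos], `/`)
  x[, !pos] <- 0
  x
}

std_error <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x)))
    stop(sprintf("%s contains %d non-finite values", what, sum(!is.finite(x))), call. = FALSE)
  invisible(x)
}
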