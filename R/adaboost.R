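# Adaptive boosting with a regularized logistic weak learner: sequential
# reweighting of misclassified time points, weak learner refit on the
# reweighted sample each round.

# Weighted logistic weak learner. L2/unpenalized fits use a direct
# Newton/IRLS solve (the design here is a few dozen voxels, so the normal
# equations are cheap and exactly deterministic); L1 goes through glmnet.
# C follows the usual inverse-regularization convention: larger C = weaker
# penalty, lambda = 1/C on the summed-loss scale.
fit_weak_logistic <- function(x, y01, w, penalty, C, max_iterations) {
  n <- nrow(x); p <- ncol(x)
  if (penalty == "l1") {
    xx <- if (p == 1) cbind(x, 0) else x
    # glmnet's maxit counts coordinate-descent passes, roughly two orders of
    # magnitude more granular than Newton iterations; rescale the cap
    fit <- glmnet::glmnet(xx, factor(y01, levels = c(0, 1)), family = "binomial",
                          weights = w * n, alpha = 1, lambda = 1 / (C * n),
                          standardize = FALSE, maxit = 100 * max_iterations)
    return(structure(list(kind = "glmnet", fit = fit, padded = p == 1),
                     class = "weak_logistic"))
  }
  lambda <- if (penalty == "none") 1e-8 else 1 / C
  ws <- w * n                      # weights on the summed-loss scale
  beta <- numeric(p + 1)           # intercept first
  xi <- cbind(1, x)
  pen <- diag(c(0, rep(lambda, p)))  # intercept unpenalized
  for (it in seq_len(min(max_iterations, 50L))) {
    eta <- pmin(pmax(drop(xi %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    wt <- ws * mu * (1 - mu)
    wt <- pmax(wt, 1e-10)
    grad <- crossprod(xi, ws * (y01 - mu)) - pen %*% beta
    hess <- crossprod(xi * wt, xi) + pen
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta_new <- beta + drop(step)
    if (max(abs(beta_new - beta)) < 1e-8 * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  structure(list(kind = "irls", beta = beta), class = "weak_logistic")
}

predict_weak <- function(model, newx) {
  if (model$kind == "glmnet") {
    xx <- if (model$padded) cbind(newx, 0) else newx
    drop(stats::predict(model$fit, xx, type = "response")) > 0.5
  } else {
    eta <- drop(cbind(1, newx) %*% model$beta)
    eta > 0
  }
}

#' Fit an AdaBoost ensemble with a logistic base estimator
#'
#' Binary adaptive boosting: time points misclassified by the current weak
#' learner are up-weighted and the regularized logistic base estimator is
#' refit, for up to `n_estimators` rounds. The fit is deterministic.
#'
#' @param x Numeric feature matrix (time points x voxels).
#' @param y Binary labels (factor or character).
#' @param n_estimators Maximum boosting rounds (grid: 10, 50, 100, 150).
#' @param learning_rate Shrinkage on each round's vote weight (0.05, 1, 2).
#' @param penalty Weak-learner regularization: `"l1"`, `"l2"` or `"none"`.
#' @param C Inverse regularization strength (0.5, 1, 2).
#' @param max_iterations Weak-learner optimizer iteration cap (100, 500, 1000).
#' @param seed Accepted for interface symmetry; the fit itself is
#'   deterministic.
#' @return An object of class `adaboost_logistic` with a `predict` method
#'   exposing per-time-point predictions.
#' @export
adaboost_logistic <- function(x, y, n_estimators = 50, learning_rate = 1,
                              penalty = c("l2", "l1", "none"), C = 1,
                              max_iterations = 100, seed = NULL) {
  penalty <- match.arg(penalty)
  x <- as.matrix(x)
  assert_finite(x, "feature matrix")
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2)
    stop("adaboost_logistic needs exactly two classes, got ", length(classes),
         call. = FALSE)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  y01 <- as.numeric(y == classes[2])
  n <- nrow(x)
  w <- rep(1 / n, n)
  models <- list(); alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- fit_weak_logistic(x, y01, w, penalty, C, max_iterations)
    pred <- predict_weak(fit, x)
    err <- sum(w[pred != y01])
    if (err <= 0) {                      # perfect weak learner: dominant vote
      models[[length(models) + 1L]] <- fit
      alphas <- c(alphas, learning_rate * log((1 - 1e-10) / 1e-10))
      break
    }
    if (err >= 0.5) {
      if (m == 1L) {                     # keep the bare learner, stop boosting
        models[[1L]] <- fit
        alphas <- 1e-10
      }
      break
    }
    alpha <- learning_rate * log((1 - err) / err)
    models[[length(models) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y01))
    w <- w / sum(w)
  }
  structure(list(models = models, alphas = alphas, classes = classes,
                 n_estimators = n_estimators, learning_rate = learning_rate,
                 penalty = penalty, C = C, max_iterations = max_iterations),
            class = "adaboost_logistic")
}

#' Predict from an AdaBoost ensemble
#'
#' @param object An [adaboost_logistic()] fit.
#' @param newx Feature matrix.
#' @param type `"class"` for labels, `"score"` for the signed vote sum.
#' @param ... Unused.
#' @return Character labels or numeric scores, one per row of `newx`.
#' @export
predict.adaboost_logistic <- function(object, newx, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  score <- numeric(nrow(newx))
  for (m in seq_along(object$models)) {
    h <- predict_weak(object$models[[m]], newx)
    score <- score + object$alphas[m] * (2 * h - 1)
  }
  if (type == "score") return(score)
  ifelse(score > 0, object$classes[2], object$classes[1])
}

#' @export
print.adaboost_logistic <- function(x, ...) {
  cat(sprintf("<adaboost_logistic> %d/%d rounds kept, penalty %s, C %.2g, learning_rate %.2g\n",
              length(x$models), x$n_estimators, x$penalty, x$C, x$learning_rate))
  invisible(x)
}
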