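## Linear maximum-margin binary classifier (L2-regularized squared-hinge
## SVM) trained by smooth quasi-Newton optimization.  Deterministic: the
## objective is strictly convex and optimization starts from zero.  Class
## weights balance unequal window counts (13 MI vs 5 rest windows per
## trial); the decision threshold is 0 and exact ties are mapped to the
## second (non-Gait) class, preferring inaction.

#' Fit a linear maximum-margin classifier
#'
#' Minimizes \code{0.5 ||w||^2 + C sum cw_i max(0, 1 - y_i f(x_i))^2} with
#' \code{f(x) = w.x + b} on standardized features; \code{cw} are inverse
#' class-frequency weights.  The first factor level is the positive class.
#'
#' @param X trials x features matrix; @param y labels (2 levels; the first
#'   level, conventionally Gait MI, is the positive class).
#' @param cost regularization constant C (default 1).
#' @param balanced use inverse-frequency class weights.
#' @return object of class \code{linear_svm}.
#' @export
fit_linear_svm <- function(X, y, cost = 1, balanced = TRUE) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("need exactly two classes")
  ys <- ifelse(y == levels(y)[1], 1, -1)
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[sdv < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  n <- nrow(Xs); d <- ncol(Xs)
  cw <- if (balanced) n / (2 * table(ys)[as.character(ys)]) else rep(1, n)
  cw <- as.numeric(cw)
  obj <- function(th) {
    w <- th[1:d]; b <- th[d + 1]
    m <- pmax(0, 1 - ys * (Xs %*% w + b))
    0.5 * sum(w^2) + cost * sum(cw * m^2)
  }
  grad <- function(th) {
    w <- th[1:d]; b <- th[d + 1]
    m <- pmax(0, 1 - ys * (drop(Xs %*% w) + b))
    g <- -2 * cost * cw * m * ys
    c(w + drop(t(Xs) %*% g), sum(g))
  }
  fit <- stats::optim(rep(0, d + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(w = fit$par[1:d], b = fit$par[d + 1], mu = mu, sd = sdv,
                 levels = levels(y), cost = cost),
            class = "linear_svm")
}

#' Decision values of a linear classifier
#' @param model a \code{linear_svm}; @param X trials x features matrix.
#' @return numeric decision values (positive = first class).
#' @export
decision_linear_svm <- function(model, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  drop(Xs %*% model$w) + model$b
}

#' Predict labels with a linear classifier
#'
#' Exact zeros of the decision function map to the second (negative,
#' non-Gait) class.
#' @inheritParams decision_linear_svm
#' @return character vector of predicted labels.
#' @export
predict_linear_svm <- function(model, X) {
  d <- decision_linear_svm(model, X)
  ifelse(d > 0, model$levels[1], model$levels[2])
}
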