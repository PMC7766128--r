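## Mutual-information based best individual feature (MIBIF) selection:
## rank the FBCSP features by estimated mutual information with the binary
## class label and keep the top k (k = 4..10 by default), optionally
## completing each selected CSP component with its within-band mirror.

#' Mutual information between a feature and a binary label
#'
#' The continuous feature is discretized by equal-frequency (quantile)
#' binning with \code{min(8, floor(sqrt(n)))} bins, then the exact discrete
#' mutual information sum \code{sum p(x,y) log2(p(x,y)/(p(x)p(y)))} is
#' evaluated.  Deterministic, in bits; a constant feature has MI 0.
#'
#' @param x numeric feature values (one per trial).
#' @param y labels (two classes, at least 2 trials per class).
#' @param bins number of quantile bins (default as above).
#' @return estimated mutual information in bits.
#' @export
mutual_information <- function(x, y,
                               bins = min(8, floor(sqrt(length(x))))) {
  y <- as.factor(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (min(table(y)) < 2) stop("need at least 2 trials per class")
  ux <- unique(x)
  if (length(ux) <= 1) return(0)      # constant feature
  if (length(ux) <= bins) {
    ## effectively discrete feature: bin by its values (quantile breaks
    ## would merge distinct atoms and bias the estimate down)
    xd <- factor(x)
  } else {
    br <- unique(stats::quantile(x,
                                 probs = seq(0, 1, length.out = bins + 1)))
    xd <- cut(x, breaks = c(-Inf, br[-c(1, length(br))], Inf))
  }
  joint <- table(xd, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
  }
  max(mi, 0)
}

#' Rank features by mutual information with the label
#'
#' @param X trials x features numeric matrix (no missing values).
#' @param y binary labels.
#' @return object of class \code{mi_ranking}: \code{mi} (bits, per
#'   feature) and \code{order} (descending-MI permutation; ties broken by
#'   lower feature index).
#' @export
rank_features <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing feature values")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  mi <- apply(X, 2, mutual_information, y = y)
  structure(list(mi = mi, order = order(-mi, seq_along(mi))),
            class = "mi_ranking")
}

#' Select the top-k features (with optional CSP pair completion)
#'
#' Keeps the k best-ranked features.  With \code{pair_completion} each
#' selected CSP component drags in its within-band mirror (component 1 with
#' 4, 2 with 3), possibly growing the selection past k -- the filter-bank
#' CSP convention, since the two mirrored components carry the two class
#' variance extremes.
#'
#' @param ranking an \code{mi_ranking}; @param k number of features
#'   (1..n_features, nominally 4..10); @param pair_completion logical.
#' @param comps_per_band CSP components per band in the feature layout.
#' @return object of class \code{feature_selection}: sorted unique
#'   \code{indices}, plus \code{k} and the flag.
#' @export
select_features <- function(ranking, k, pair_completion = TRUE,
                            comps_per_band = 4) {
  nf <- length(ranking$mi)
  if (k < 1 || k > nf) stop("k must be in 1..", nf)
  top <- ranking$order[seq_len(k)]
  idx <- top
  if (pair_completion) {
    band <- (top - 1) %/% comps_per_band
    comp <- (top - 1) %% comps_per_band + 1
    mirror <- band * comps_per_band + (comps_per_band + 1 - comp)
    idx <- unique(c(top, mirror))
  }
  structure(list(indices = sort(idx), k = k,
                 pair_completion = pair_completion),
            class = "feature_selection")
}

#' Choose k by stratified cross-validation
#'
#' Evaluates each candidate k with stratified cross-validated accuracy of
#' the downstream linear classifier on the training features and returns
#' the k maximizing it (ties go to the smaller k).
#'
#' @param X trials x features matrix; @param y binary labels;
#' @param candidates candidate k values (default 4:10);
#' @param folds number of CV folds; @param pair_completion passed through.
#' @return the chosen k.
#' @export
choose_k <- function(X, y, candidates = 4:10, folds = 5,
                     pair_completion = TRUE) {
  y <- as.factor(y)
  if (min(table(y)) < 10) stop("need at least 10 trials per class")
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    fold_of[i] <- rep_len(seq_len(folds), length(i))
  }
  acc <- sapply(candidates, function(k) {
    hits <- 0
    for (f in seq_len(folds)) {
      tr <- fold_of != f; te <- !tr
      rk <- rank_features(X[tr, , drop = FALSE], y[tr])
      sel <- select_features(rk, k, pair_completion)$indices
      mdl <- fit_linear_svm(X[tr, sel, drop = FALSE], y[tr])
      hits <- hits + sum(predict_linear_svm(mdl,
                                            X[te, sel, drop = FALSE]) == y[te])
    }
    hits / length(y)
  })
  candidates[which.max(acc)]     # which.max takes the first (smallest k) tie
}
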