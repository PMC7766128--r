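## Filter-bank common spatial patterns: six-band zero-phase Butterworth
## filtering, per-band CSP spatial filters, and log-normalized band-power
## features (4 components per band, 24 features for the default bank).

#' Filter bank specification
#'
#' @param bands list of c(low, high) pairs in Hz; the default is the
#'   six-band mu-to-low-gamma bank 7-9, 10-12, 13-15, 16-20, 21-25,
#'   26-34 Hz.
#' @param order Butterworth prototype order (applied forward-backward, so
#'   the effective attenuation order is doubled).
#' @return object of class \code{filter_bank}.
#' @export
filter_bank <- function(bands = list(c(7, 9), c(10, 12), c(13, 15),
                                     c(16, 20), c(21, 25), c(26, 34)),
                        order = 4) {
  for (b in bands)
    if (length(b) != 2 || b[1] >= b[2])
      stop("each band must be c(low, high) with low < high")
  if (order %% 2 != 0) stop("filter order must be even")
  structure(list(bands = bands, order = order), class = "filter_bank")
}

#' Zero-phase bandpass filtering of an epoch
#'
#' @param epoch list with \code{data} (channels x samples) and \code{fs}.
#' @param band c(low, high) Hz; @param order Butterworth order.
#' @return epoch with filtered data.
#' @export
bandpass <- function(epoch, band, order = 4) {
  flt <- butter_bandpass(band[1], band[2], epoch$fs, order)
  epoch$data <- t(filtfilt(t(epoch$data), flt))
  epoch
}

## normalized spatial covariance of one (already band-filtered) epoch
epoch_cov <- function(E) {
  C <- tcrossprod(E)
  C / sum(diag(C))
}

## shrinkage toward a scaled identity; C is trace-normalized
shrink_cov <- function(C, lambda) {
  N <- nrow(C)
  (1 - lambda) * C + lambda * (sum(diag(C)) / N) * diag(N)
}

#' Fit a common spatial pattern model for one class pair
#'
#' Computes the full projection matrix W whose rows simultaneously
#' diagonalize the two class-average normalized spatial covariances,
#' ordered by descending class-A variance ratio; the first two and last two
#' rows are marked as the selected components.
#'
#' @param epochs_A,epochs_B lists of epochs (or of precomputed covariance
#'   matrices) for the two classes; at least two per class.
#' @param shrinkage identity-shrinkage weight for the class covariances.
#' @return object of class \code{csp_model}: \code{W} (N x N, rows =
#'   components), \code{var_ratio} (class-A variance ratios, descending),
#'   \code{selected_rows}.
#' @export
fit_csp <- function(epochs_A, epochs_B, shrinkage = 1e-4) {
  as_cov <- function(e) if (is.matrix(e)) e else epoch_cov(e$data)
  if (length(epochs_A) < 2 || length(epochs_B) < 2)
    stop("need at least 2 epochs per class")
  CA <- Reduce(`+`, lapply(epochs_A, as_cov)) / length(epochs_A)
  CB <- Reduce(`+`, lapply(epochs_B, as_cov)) / length(epochs_B)
  if (nrow(CA) != nrow(CB)) stop("channel counts differ between classes")
  CA <- shrink_cov(CA, shrinkage); CB <- shrink_cov(CB, shrinkage)
  Cc <- CA + CB
  eg <- eigen(Cc, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  if (any(eg$values < tol)) {
    warning("rank-deficient composite covariance; clamping ",
            sum(eg$values < tol), " eigenvalue(s)")
    eg$values <- pmax(eg$values, tol)
  }
  P <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  S <- P %*% CA %*% t(P)
  S <- (S + t(S)) / 2
  eg2 <- eigen(S, symmetric = TRUE)       # eigenvalues descending in R
  W <- t(eg2$vectors) %*% P
  N <- nrow(W)
  structure(list(W = W, var_ratio = eg2$values,
                 selected_rows = c(1, 2, N - 1, N), n_channels = N),
            class = "csp_model")
}

#' Apply a CSP model to an epoch
#'
#' @param epoch epoch whose data is already filtered to the model's band.
#' @param model a \code{csp_model}.
#' @param rows which rows of W to apply (default: the selected components).
#' @return projected signals Z (length(rows) x T).
#' @export
apply_csp <- function(epoch, model, rows = model$selected_rows) {
  if (nrow(epoch$data) != model$n_channels)
    stop("epoch has ", nrow(epoch$data), " channels, model expects ",
         model$n_channels)
  model$W[rows, , drop = FALSE] %*% epoch$data
}

#' Fit the full filter-bank CSP model
#'
#' One CSP model per sub-band, each fit on that band's zero-phase filtered
#' epochs.  Class A is the first-named class of the pair.
#'
#' @param epochs list of epochs with \code{label} fields.
#' @param labels optional label vector (defaults to epoch labels).
#' @param pair length-2 character vector (class A, class B).
#' @param bank a \code{filter_bank}; @param shrinkage see [fit_csp()].
#' @return object of class \code{fbcsp_model} with one \code{csp_model} per
#'   band; feature layout is band-major (4 components per band).
#' @export
fit_fbcsp <- function(epochs, labels = NULL, pair, bank = filter_bank(),
                      shrinkage = 1e-4) {
  if (is.null(labels)) labels <- vapply(epochs, `[[`, "", "label")
  if (!all(pair %in% labels))
    stop("both classes of the pair must be present in the labels")
  if (any(table(factor(labels[labels %in% pair], levels = pair)) < 2))
    stop("need at least 2 epochs per class")
  covs <- fb_covariances(epochs, bank)
  fit_fbcsp_cov(covs, labels, pair, bank, shrinkage)
}

#' Precompute per-band spatial covariances of a window set
#'
#' Filtering and covariance estimation are by far the dominant cost of
#' FBCSP training; they depend only on the data, not on the class split,
#' so resampling schemes (bootstrap, cross-validation) can reuse them.
#'
#' @param epochs list of epochs; @param bank a \code{filter_bank}.
#' @return object of class \code{fb_covs}: list of per-band arrays
#'   (N x N x n_windows) of trace-normalized covariances.
#' @export
fb_covariances <- function(epochs, bank = filter_bank()) {
  N <- nrow(epochs[[1]]$data)
  T_ <- ncol(epochs[[1]]$data)
  fs <- epochs[[1]]$fs
  nw <- length(epochs)
  out <- lapply(bank$bands, function(b) array(0, c(N, N, nw)))
  ## batch the zero-phase filtering: windows are independent columns, so
  ## filtering a [T x N*chunk] matrix equals filtering each epoch alone
  chunk <- max(1L, min(nw, floor(4e6 / (T_ * N))))
  for (s in seq(1, nw, by = chunk)) {
    idx <- s:min(nw, s + chunk - 1)
    X <- matrix(0, T_, N * length(idx))
    for (j in seq_along(idx)) {
      E <- epochs[[idx[j]]]$data
      ## pre-normalize each window by its global RMS: the features are
      ## scale-invariant by construction, and removing the scale before
      ## the near-unit-circle IIR recursion keeps them scale-invariant
      ## numerically as well (rounding differences would otherwise be
      ## amplified by the narrow-band filters)
      r <- sqrt(mean(E^2))
      if (r > 0) E <- E / r
      X[, (j - 1) * N + 1:N] <- t(E)
    }
    for (b in seq_along(bank$bands)) {
      band <- bank$bands[[b]]
      flt <- butter_bandpass(band[1], band[2], fs, bank$order)
      Xf <- filtfilt(X, flt)
      for (j in seq_along(idx)) {
        C <- crossprod(Xf[, (j - 1) * N + 1:N, drop = FALSE])
        out[[b]][, , idx[j]] <- C / sum(diag(C))
      }
    }
  }
  structure(list(covs = out, bank = bank), class = "fb_covs")
}

## FBCSP fit from precomputed covariances (fast path; same estimator)
fit_fbcsp_cov <- function(fbc, labels, pair, bank = fbc$bank,
                          shrinkage = 1e-4) {
  iA <- which(labels == pair[1]); iB <- which(labels == pair[2])
  if (length(iA) < 2 || length(iB) < 2)
    stop("need at least 2 epochs per class")
  models <- lapply(fbc$covs, function(arr) {
    N <- dim(arr)[1]
    M <- matrix(arr, N * N)
    CA <- matrix(rowMeans(M[, iA, drop = FALSE]), N)
    CB <- matrix(rowMeans(M[, iB, drop = FALSE]), N)
    fit_csp(list(CA, CA), list(CB, CB), shrinkage)
  })
  structure(list(bank = bank, csp = models, pair = pair,
                 n_features = 4L * length(bank$bands)),
            class = "fbcsp_model")
}

#' Extract log-normalized FBCSP features from one epoch
#'
#' For each band, the epoch is zero-phase filtered, projected onto the four
#' selected CSP components, and each component's power is log-normalized by
#' the summed power of the four:
#' \code{f_j = log(p_j / sum(p))}.  Features are returned band-major
#' (24 values for the default bank); \code{exp(f)} sums to 1 within each
#' band.
#'
#' @param epoch epoch (unfiltered); @param fb_model an \code{fbcsp_model}.
#' @return numeric feature vector of length \code{fb_model$n_features}.
#' @export
extract_features <- function(epoch, fb_model) {
  fbc <- fb_covariances(list(epoch), fb_model$bank)
  drop(features_from_cov(fbc, fb_model))
}

## features for every window in an fb_covs object: n_windows x n_features.
## the quadratic forms w C w' are evaluated as one BLAS product per band:
## p_j(i) = vec(w_j w_j') . vec(C_i)
features_from_cov <- function(fbc, fb_model) {
  nw <- dim(fbc$covs[[1]])[3]
  out <- matrix(0, nw, fb_model$n_features)
  eps <- .Machine$double.eps
  for (b in seq_along(fbc$covs)) {
    m <- fb_model$csp[[b]]
    Wsel <- m$W[m$selected_rows, , drop = FALSE]
    N <- dim(fbc$covs[[b]])[1]
    Q <- apply(Wsel, 1, tcrossprod)          # N^2 x 4
    P <- crossprod(matrix(fbc$covs[[b]], N * N), Q)   # nw x 4
    if (any(P <= 0)) {
      warning("zero-variance CSP component; flooring")
      P <- pmax(P, eps)
    }
    out[, (b - 1) * 4 + 1:4] <- log(P / rowSums(P))
  }
  out
}
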