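# MIBIF: mutual-information estimator against exact discrete sums,
# ranking, selection with pair completion, k choice.

test_that("mutual information matches exact values on canonical joints", {
  set.seed(20)
  y <- rep(0:1, each = 1000)
  # independent feature: MI near zero
  expect_lt(mutual_information(rnorm(2000), y), 0.02)
  # feature equal to the label: exactly 1 bit
  expect_equal(mutual_information(as.numeric(y), y), 1)
  # 2x2 joint {(0,0):.4,(0,1):.1,(1,0):.1,(1,1):.4} -- brute-force sum
  p <- c(0.4, 0.1, 0.1, 0.4)
  px <- c(0.5, 0.5); py <- c(0.5, 0.5)
  oracle <- sum(p * log2(p / c(px[1] * py[1], px[1] * py[2],
                               px[2] * py[1], px[2] * py[2])))
  x <- c(rep(0, 400), rep(1, 100), rep(0, 100), rep(1, 400))
  yy <- rep(0:1, each = 500)
  expect_equal(mutual_information(x, yy), oracle, tolerance = 1e-12)
  # constant feature
  expect_equal(mutual_information(rep(2, 100), rep(0:1, 50)), 0)
  expect_error(mutual_information(1:3, c(0, 0, 1)), "2 trials")
})

test_that("the estimator tracks the exact sum on random discrete joints", {
  set.seed(21)
  for (rep in 1:5) {
    pj <- matrix(stats::rgamma(6, 1), 3, 2)
    pj <- pj / sum(pj)
    n <- 1e4
    cells <- sample(6, n, replace = TRUE, prob = as.vector(pj))
    x <- (cells - 1) %% 3
    y <- (cells - 1) %/% 3
    emp <- table(x, y) / n
    exact <- 0
    for (i in 1:3) for (j in 1:2) {
      pij <- emp[i, j]
      if (pij > 0)
        exact <- exact + pij * log2(pij / (sum(emp[i, ]) * sum(emp[, j])))
    }
    expect_lt(abs(mutual_information(x, y) - exact), 0.01)
  }
})

test_that("label-independent noise does not inflate MI", {
  set.seed(22)
  y <- rep(0:1, each = 150)
  x <- c(rnorm(150), rnorm(150, 2))
  base <- mutual_information(x, y)
  deltas <- replicate(20, {
    mutual_information(x + rnorm(300, sd = 2), y) - base
  })
  expect_lt(mean(deltas), 0.02)
})

test_that("ranking sorts by MI with index tie-breaks", {
  set.seed(23)
  y <- rep(c("A", "B"), each = 100)
  X <- matrix(rnorm(200 * 24), 200, 24)
  X[, 17] <- ifelse(y == "A", 1, 0) + rnorm(200, sd = 0.01)
  r <- rank_features(X, y)
  expect_equal(r$order[1], 17)
  expect_length(r$mi, 24)
  expect_setequal(r$order, 1:24)
  expect_true(all(r$mi >= 0))
  # all-identical features: identity permutation by tie-break
  Xc <- matrix(rep(rnorm(200), 24), 200, 24)
  expect_equal(rank_features(Xc, y)$order, 1:24)
  expect_error(rank_features(X, rep("A", 200)), "single class")
  X[1, 1] <- NA
  expect_error(rank_features(X, y), "missing")
})

test_that("ranking is stable under monotone feature transforms", {
  set.seed(24)
  y <- rep(0:1, each = 200)
  X <- cbind(c(rnorm(200), rnorm(200, 1.5)),
             c(rnorm(200), rnorm(200, 0.5)),
             rnorm(400))
  r1 <- rank_features(X, y)$order
  X2 <- cbind(exp(X[, 1]), X[, 2]^3 + 2 * X[, 2], X[, 3])
  expect_equal(rank_features(X2, y)$order, r1)
})

test_that("selection keeps top-k and completes CSP mirrors", {
  rk <- structure(list(mi = seq(24, 1) / 24, order = 1:24),
                  class = "mi_ranking")
  s <- select_features(rk, 4, pair_completion = FALSE)
  expect_equal(s$indices, 1:4)
  expect_equal(select_features(rk, 24, FALSE)$indices, 1:24)
  # ranks 1-4 are components 1,2,3,4 of band 1: mirrors are 4,3,2,1 -> no growth
  expect_equal(select_features(rk, 4, TRUE)$indices, 1:4)
  # ranks all "first" components of four bands -> mirrors double the set
  rk2 <- structure(list(mi = rep(0, 24), order = c(c(1, 5, 9, 13),
                                                   setdiff(1:24,
                                                           c(1, 5, 9, 13)))),
                   class = "mi_ranking")
  s2 <- select_features(rk2, 4, TRUE)
  expect_length(s2$indices, 8)
  expect_setequal(s2$indices, c(1, 4, 5, 8, 9, 12, 13, 16))
  expect_error(select_features(rk, 0), "k must be")
  expect_error(select_features(rk, 25), "k must be")
})

test_that("choose_k lands in range and near the oracle grid", {
  set.seed(25)
  n <- 60
  y <- factor(rep(c("A", "B"), each = n / 2), levels = c("A", "B"))
  X <- matrix(rnorm(n * 24), n, 24)
  sig <- c(1, 4, 5, 8, 9, 12)            # six informative features
  for (j in sig) X[, j] <- X[, j] + ifelse(y == "A", 1.2, 0)
  k <- choose_k(X, y, candidates = 4:10)
  expect_true(k %in% 4:10)
  # CV accuracy at chosen k is within 2 points of the best candidate
  cv_acc <- function(kk) {
    hits <- 0
    for (f in 1:5) {
      te <- seq_len(n) %% 5 == (f - 1)
      rk <- rank_features(X[!te, ], y[!te])
      sel <- select_features(rk, kk)$indices
      m <- fit_linear_svm(X[!te, sel, drop = FALSE], y[!te])
      hits <- hits + sum(predict_linear_svm(m, X[te, sel, drop = FALSE]) ==
                           y[te])
    }
    hits / n
  }
  accs <- vapply(4:10, cv_acc, 0)
  expect_gte(cv_acc(k) + 0.02, max(accs))
  # pure noise: smallest candidate by tie-break tendency
  set.seed(26)
  Xn <- matrix(rnorm(n * 24), n, 24)
  kn <- choose_k(Xn, y, candidates = 4:10)
  expect_true(kn %in% 4:10)
  expect_error(choose_k(X[1:10, ], y[1:10]), "10 trials")
})
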