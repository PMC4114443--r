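random_features <- function(n = 20, p = 9, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(rnorm(3 * p), 3, p)
  base %*% load + 0.3 * matrix(rnorm(n * p), n, p)
}

test_that("standardization centres, scales and is idempotent", {
  T <- random_features(seed = 2)
  colnames(T) <- paste0("T", 1:9)
  Z <- standardize(T)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(apply(Z, 2, sd), rep(1, 9), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(standardize(Z), Z, tolerance = 1e-12)
  # affine-related columns standardize identically
  T2 <- T
  T2[, 2] <- 3 * T[, 1] - 7
  Z2 <- standardize(T2)
  expect_equal(Z2[, 1], Z2[, 2], tolerance = 1e-12)
  # zero-variance column is refused by name
  T3 <- T
  T3[, 5] <- 4
  expect_error(standardize(T3), "T5")
})

test_that("the correlation matrix is the Pearson matrix over ROI rows", {
  # frozen hand evaluation of the Pearson formula on a 3-row toy matrix
  T <- cbind(a = c(1, 2, 4), b = c(2, 1, 5), c = c(0, 1, 0))
  R <- correlation_matrix(T)
  expect_equal(unname(R["a", "b"]), 0.8386278694, tolerance = 1e-9)
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 3))
  # duplicated columns correlate exactly 1
  T2 <- random_features(seed = 3)
  T2[, 2] <- T2[, 1]
  expect_equal(unname(stats::cor(T2)[1, 2]), 1)
  # identity R = Z'Z/(n-1) for standardized features
  T3 <- random_features(seed = 4)
  Z <- standardize(T3)
  expect_equal(correlation_matrix(T3), t(Z) %*% Z / (nrow(Z) - 1), ignore_attr = TRUE)
  expect_error(correlation_matrix(T[1:2, ]), "3 rows")
})

test_that("eigendecomposition is sorted, orthonormal and sign-fixed", {
  R <- correlation_matrix(random_features(seed = 5))
  eig <- eigendecompose(R)
  expect_false(is.unsorted(rev(eig$values)))
  expect_equal(sum(eig$values), 9, tolerance = 1e-8)
  expect_equal(t(eig$vectors) %*% eig$vectors, diag(9), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(colSums(eig$vectors) >= -1e-10))
  # reconstruction R = sum_i lambda_i l_i l_i'
  recon <- eig$vectors %*% diag(eig$values) %*% t(eig$vectors)
  expect_equal(recon, R, tolerance = 1e-8, ignore_attr = TRUE)
  # identity correlation: all eigenvalues 1
  eye <- eigendecompose(diag(9))
  expect_equal(eye$values, rep(1, 9))
  # embedded 2x2 correlated block has leading eigenvalue 1 + |r|
  r <- 0.73
  Rb <- diag(9)
  Rb[1, 2] <- Rb[2, 1] <- r
  eb <- eigendecompose(Rb)
  expect_equal(eb$values[1], 1 + r, tolerance = 1e-10)
  expect_error(eigendecompose(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})

test_that("contribution rates and the CCR selection rule behave as specified", {
  rates <- contribution_rates(rep(1, 9))
  expect_equal(rates$cr, rep(1 / 9, 9))
  expect_equal(rates$ccr, (1:9) / 9)
  r1 <- contribution_rates(c(9, rep(0, 8)))
  expect_equal(r1$cr[1], 1)
  expect_equal(r1$ccr[1], 1)
  R <- correlation_matrix(random_features(seed = 6))
  rr <- contribution_rates(eigendecompose(R)$values)
  expect_false(is.unsorted(rr$ccr))
  expect_equal(rr$ccr[9], 1)

  expect_identical(select_components(c(0.70, 0.85, 0.95, 1), 0.80), 2L)
  expect_identical(select_components(c(0.97, 0.99, 1), 0.80), 1L)
  expect_identical(select_components((1:9) / 9, 0.80), 8L)
  expect_error(contribution_rates(rep(0, 9)))
})

test_that("scores have eigenvalue variances and the documented special cases", {
  T <- random_features(seed = 7)
  colnames(T) <- paste0("T", 1:9)
  Z <- standardize(T)
  eig <- eigendecompose(correlation_matrix(T))
  sc <- principal_scores(Z, eig$vectors, 9)
  expect_equal(unname(apply(sc, 2, var)), eig$values, tolerance = 1e-6)
  # empirical covariance of scores is diag(lambda)
  expect_equal(unname(cov(sc)), diag(eig$values), tolerance = 1e-6)
  # a centred datum scores zero on every component
  expect_equal(unname(principal_scores(matrix(0, 1, 9), eig$vectors, 3)), matrix(0, 1, 3))
  # identity R with basis loadings returns the features themselves
  expect_equal(unname(principal_scores(Z, diag(9), 9)), unname(Z))
  expect_error(principal_scores(Z[, 1:5], eig$vectors, 2), "dimension")
})

test_that("the (F1+F2) rule thresholds at 8.5 with the cancer boundary", {
  mk <- function(m) matrix(c(m / 2, m / 2), 1, 2)
  expect_identical(classify_region(mk(8.69))$label, "normal")
  expect_identical(classify_region(mk(7.27))$label, "cancer")
  expect_identical(classify_region(mk(8.5))$label, "cancer")
  sc <- cbind(F1 = c(5, 6, 7), F2 = c(4, 4, 4))
  out <- classify_region(sc)
  expect_equal(out$score_mean, 10)
  expect_equal(out$score_sd, 1)
  expect_identical(out$label, "normal")
  expect_error(classify_region(sc[, 1, drop = FALSE]), "2 principal")
})

test_that("PCA summaries are invariant to ROI row permutation", {
  T <- random_features(seed = 8)
  colnames(T) <- paste0("T", 1:9)
  rep1 <- pca_report(T)
  rep2 <- pca_report(T[sample(nrow(T)), ])
  expect_equal(rep1$eigenvalues, rep2$eigenvalues)
  expect_equal(rep1$ccr, rep2$ccr)
  expect_equal(rep1$sum_mean, rep2$sum_mean)
  # standardized per-specimen scores are mean-centred by construction
  expect_equal(rep1$F1_mean, 0, tolerance = 1e-10)
  expect_equal(rep1$sum_mean, 0, tolerance = 1e-10)
  # raw-path scores need not be centred
  rep3 <- pca_report(abs(T) + 5, score_features = "raw")
  expect_gt(abs(rep3$sum_mean), 0.1)
})

test_that("uniformity orientation makes the T1 loading non-negative", {
  eig <- eigendecompose(correlation_matrix(random_features(seed = 9)))
  or <- orient_uniformity(eig$vectors)
  expect_true(all(or[1, ] >= -1e-10))
  # orientation only flips signs; column spans are unchanged
  expect_equal(abs(or), abs(eig$vectors), tolerance = 1e-12)
})
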