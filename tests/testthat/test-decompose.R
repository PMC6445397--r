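test_that("PCA satisfies the reconstruction identity and orthonormality", {
  set.seed(31)
  vals <- matrix(rnorm(10 * 6), 10, 6,
                 dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  res <- run_pca(vals)
  # full-rank reconstruction: scores . loadings' + feature means = input'
  recon <- res$scores %*% t(res$loadings) +
    matrix(rowMeans(vals), ncol(vals), nrow(vals), byrow = TRUE)
  expect_equal(recon, t(vals), tolerance = 1e-8, ignore_attr = TRUE)
  # orthonormal loadings, uncorrelated scores
  expect_equal(crossprod(res$loadings), diag(ncol(res$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  cc <- crossprod(scale(res$scores, center = TRUE, scale = FALSE))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  # variance ratios non-increasing in [0, 1], summing to <= 1
  evr <- res$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-8)
  # sign convention: largest-magnitude loading positive in each component
  for (j in seq_len(ncol(res$loadings))) {
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  }
})

test_that("PCA matches a covariance-eigendecomposition oracle up to sign", {
  set.seed(32)
  for (i in 1:5) {
    nf <- sample(5:20, 1); ns <- sample(4:20, 1)
    vals <- matrix(rnorm(nf * ns), nf, ns)
    res <- run_pca(vals)
    eig <- eigen(stats::cov(t(vals)), symmetric = TRUE)
    k <- sum(eig$values > 1e-10)
    for (j in seq_len(min(k, ncol(res$loadings)))) {
      v <- eig$vectors[, j]
      expect_equal(abs(sum(v * res$loadings[, j])), 1, tolerance = 1e-6)
    }
    expect_equal(res$explained_variance_ratio,
                 pmax(eig$values, 0)[seq_along(res$explained_variance_ratio)] /
                   sum(pmax(eig$values, 0)),
                 tolerance = 1e-8)
  }
})

test_that("PCA handles degenerate inputs as defined", {
  # samples on a line -> first ratio 1, rest 0
  base <- rnorm(6)
  vals <- outer(base, c(1, 2, 3, 4))
  res <- run_pca(vals)
  expect_equal(res$explained_variance_ratio[1], 1)
  expect_equal(res$explained_variance_ratio[-1],
               rep(0, length(res$explained_variance_ratio) - 1),
               tolerance = 1e-12)
  # all-constant features -> all ratios 0
  expect_equal(run_pca(matrix(5, 4, 3))$explained_variance_ratio,
               rep(0, 3))
  # missing values refused with advice
  bad <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(run_pca(bad), "build_matrix")
  expect_error(run_pca(matrix(rnorm(12), 4, 3), n_components = 4),
               "n_components")
})

test_that("loading selection partitions by signed threshold, boundary inclusive", {
  res <- structure(list(loadings = cbind(c(0.5, -0.5, 0.0, 0.025, -0.025)),
                        feature_ids = paste0("f", 1:5)),
                   class = "meth_pca")
  sel <- select_by_loading(res, 1, threshold = 2.5e-2)
  expect_equal(sel$positive_ids, c("f1", "f4"))
  expect_equal(sel$negative_ids, c("f2", "f5"))
  expect_length(intersect(sel$positive_ids, sel$negative_ids), 0L)
  # threshold above the largest magnitude -> both sets empty
  sel2 <- select_by_loading(res, 1, threshold = 0.9)
  expect_length(sel2$positive_ids, 0L)
  expect_length(sel2$negative_ids, 0L)
  expect_error(select_by_loading(res, 1, threshold = 0), "threshold")
  expect_error(select_by_loading(res, 2), "pc_index")
})

test_that("selection is invariant to a global sign flip of the data", {
  set.seed(33)
  vals <- matrix(rnorm(40 * 8), 40, 8,
                 dimnames = list(paste0("f", 1:40), paste0("s", 1:8)))
  s1 <- select_by_loading(run_pca(vals), 2, 0.1)
  s2 <- select_by_loading(run_pca(-vals), 2, 0.1)
  expect_equal(s1$positive_ids, s2$positive_ids)
  expect_equal(s1$negative_ids, s2$negative_ids)
})

test_that("k-means recovers separated blobs and is deterministic", {
  set.seed(34)
  blob1 <- matrix(rnorm(20 * 4, mean = 0), 20, 4)
  blob2 <- matrix(rnorm(10 * 4, mean = 12), 10, 4)
  vals <- rbind(blob1, blob2)
  rownames(vals) <- paste0("f", 1:30)
  labels <- kmeans_rows(vals, k = 2, seed = 9)
  expect_equal(unname(labels), rep(c(1L, 2L), c(20, 10)))  # sized-ordered
  # same seed -> identical labels
  expect_identical(labels, kmeans_rows(vals, k = 2, seed = 9))
  # k = n features -> singleton clusters, zero within-cluster scatter
  small <- vals[1:6, ]
  lab6 <- kmeans_rows(small, k = 6, seed = 1)
  expect_equal(sort(unname(lab6)), 1:6)
  expect_error(kmeans_rows(small, k = 7, seed = 1), "exceeds")
})

test_that("separation score is the folded AUC", {
  expect_equal(unname(separation_score(cbind(1:4), c(FALSE, FALSE, TRUE, TRUE))), 1)
  expect_equal(unname(separation_score(cbind(1:4), c(TRUE, TRUE, FALSE, FALSE))), 1)
  # interleaved ranks: 3 of 4 pairs concordant
  expect_equal(unname(separation_score(cbind(1:4), c(FALSE, TRUE, FALSE, TRUE))), 0.75)
  # identical scores: no separation
  expect_equal(unname(separation_score(cbind(rep(2, 6)), rep(c(TRUE, FALSE), 3))), 0.5)
  expect_error(separation_score(cbind(1:4), rep(TRUE, 4)), "both label classes")

  # pair-counting oracle and pROC on random data, per component
  set.seed(35)
  for (i in 1:10) {
    sc <- matrix(rnorm(24), 12, 2)
    lab <- sample(c(TRUE, FALSE), 12, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    got <- separation_score(sc, lab)
    expect_equal(unname(got[1]), auc_oracle(sc[, 1], lab), tolerance = 1e-12)
    proc <- as.numeric(pROC::auc(pROC::roc(lab, sc[, 2], quiet = TRUE,
                                           direction = "auto")))
    expect_equal(unname(got[2]), max(proc, 1 - proc), tolerance = 1e-12)
  }
})
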