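pareto_stub <- function(m) {
  hosnmr:::new_bin_matrix(m, cbind(seq_len(ncol(m)) - 1, seq_len(ncol(m))),
                          data.frame(brand = rep(c("A", "B"), length.out = nrow(m)),
                                     lot = as.character(seq_len(nrow(m)))),
                          "pareto")
}

test_that("PCA recovers rank, reconstructs, and matches an eigen oracle", {
  # rank-1 data: one pattern, varying amounts
  pattern <- c(1, -2, 3, 0.5)
  m <- outer(c(1, 2, 3, 4, 5), pattern) + 10
  p1 <- fit_pca(pareto_stub(m), 1)
  expect_equal(p1$explained_fraction[1], 1, tolerance = 1e-9)

  withr::with_seed(31, { m2 <- matrix(rnorm(60), 5, 12) })
  full <- fit_pca(pareto_stub(m2), 4)
  centered <- sweep(m2, 2, colMeans(m2))
  expect_equal(full$scores %*% t(full$loadings), centered, tolerance = 1e-8)
  expect_true(all(diff(full$explained_fraction) <= 1e-12))
  expect_equal(crossprod(full$loadings), diag(4), tolerance = 1e-8)

  # independent oracle: eigendecomposition of the covariance matrix
  ev <- eigen(cov(centered), symmetric = TRUE)
  expect_equal(apply(full$scores, 2, var), ev$values[1:4], tolerance = 1e-8)
  for (k in 1:4) {
    expect_equal(abs(sum(full$loadings[, k] * ev$vectors[, k])), 1, tolerance = 1e-8)
  }
  expect_error(fit_pca(pareto_stub(m2), 5), "n_components")
})

test_that("covariance pooling follows the lot-count-weighted form", {
  mk <- function(A, B) {
    structure(list(A = A, B = B, m = nrow(A), n = nrow(B), p = ncol(A),
                   mean_A = colMeans(A), mean_B = colMeans(B),
                   cov_A = cov(A), cov_B = cov(B)),
              class = "group_scores")
  }
  # m = n with equal covariances returns that covariance
  withr::with_seed(5, { A <- matrix(rnorm(12), 4, 3) })
  g <- mk(A, A + 100)          # shift changes means, not covariance
  expect_equal(pool_covariance(g), cov(A), tolerance = 1e-12)

  # scalar hand-arithmetic case: m=7 S_A=2, n=3 S_B=12 -> 5
  gs <- mk(matrix(0, 7, 1), matrix(0, 3, 1))
  gs$cov_A <- matrix(2); gs$cov_B <- matrix(12)
  expect_equal(pool_covariance(gs)[1, 1], 5)

  # convex combination of PSD matrices stays symmetric PSD
  withr::with_seed(6, {
    for (r in 1:5) {
      g2 <- mk(matrix(rnorm(15), 5, 3), matrix(rnorm(9), 3, 3))
      S <- pool_covariance(g2)
      expect_equal(S, t(S), tolerance = 1e-12)
      expect_true(min(eigen(S, symmetric = TRUE)$values) > -1e-10)
    }
  })
})

test_that("D_M matches the univariate closed form and basic limits", {
  g <- group_scores(matrix(c(0, 2, 3, 5), 4, 1), "A", "B",
                    brands = c("A", "A", "B", "B"))
  r <- mahalanobis_distance(g)
  # S_A = S_B = 2 -> pooled S = 2; |0-4... | means 1 and 4 -> 3/sqrt(2)
  expect_equal(r$dm, 3 / sqrt(2), tolerance = 1e-12)
  expect_identical(r$verdict, "similar")

  withr::with_seed(70, { grp <- matrix(rnorm(12), 4, 3) })
  same <- group_scores(rbind(grp, grp), "A", "B",
                       brands = rep(c("A", "B"), each = 4))
  expect_equal(mahalanobis_distance(same)$dm, 0)

  sing <- group_scores(matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 4, 2), "A", "B",
                       brands = c("A", "A", "B", "B"))
  expect_error(mahalanobis_distance(sing), "singular|ill-conditioned")
})

test_that("D_M is invariant, symmetric in groups, and monotone in separation", {
  withr::with_seed(77, {
    for (r in 1:20) {
      sc <- matrix(rnorm(30), 10, 3)
      brands <- rep(c("A", "B"), c(6, 4))
      g <- group_scores(sc, "A", "B", brands = brands)
      dm <- mahalanobis_distance(g)$dm
      # invariance under a random invertible linear map
      repeat { M <- matrix(rnorm(9), 3, 3); if (abs(det(M)) > 0.1) break }
      g2 <- group_scores(sc %*% M, "A", "B", brands = brands)
      expect_equal(mahalanobis_distance(g2)$dm, dm, tolerance = 1e-8)
      # symmetry under group exchange
      g3 <- group_scores(sc, "B", "A", brands = brands)
      expect_equal(mahalanobis_distance(g3)$dm, dm, tolerance = 1e-12)
    }
  })
  # monotone in the mean offset along a fixed direction, covariances fixed
  withr::with_seed(78, { base <- matrix(rnorm(30), 10, 3) })
  brands <- rep(c("A", "B"), each = 5)
  dir <- c(1, 2, -1)
  dms <- vapply(seq(0, 3, by = 0.5), function(delta) {
    sc <- base
    bsel <- brands == "B"
    # align group means, then separate them by exactly delta * dir
    sc[bsel, ] <- sweep(sc[bsel, ], 2,
                        colMeans(base[bsel, ]) - colMeans(base[!bsel, ]) - delta * dir,
                        "-")
    mahalanobis_distance(group_scores(sc, "A", "B", brands = brands))$dm
  }, 0.0)
  expect_true(all(diff(dms) >= -1e-10))
})

test_that("D_M estimates concentrate near the population distance", {
  # two Gaussian groups sharing Sigma, means offset along the first axis
  Sigma <- diag(c(4, 2, 1))
  delta <- c(3, 0, 0)
  pop <- sqrt(drop(t(delta) %*% solve(Sigma, delta)))  # 1.5
  withr::with_seed(55, {
    est <- replicate(200, {
      A <- matrix(rnorm(40 * 3), 40) %*% chol(Sigma)
      B <- sweep(matrix(rnorm(40 * 3), 40) %*% chol(Sigma), 2, delta, "+")
      g <- group_scores(rbind(A, B), "A", "B", brands = rep(c("A", "B"), each = 40))
      mahalanobis_distance(g)$dm
    })
  })
  expect_lt(abs(mean(est) - pop), 3 * sd(est) / sqrt(length(est)) + 0.05)
})

test_that("confidence ellipses have the stated geometry and coverage", {
  withr::with_seed(12, { sc <- matrix(rnorm(20), 10, 2) })
  ell <- confidence_ellipse(sc, 0.9)
  expect_true(in_ellipse(ell, ell$center))

  # chi-square limit for isotropic data at large m
  withr::with_seed(13, { big <- matrix(rnorm(4000), 2000, 2) })
  ell_big <- confidence_ellipse(big, 0.9)
  expect_equal(unname(sort(ell_big$semi_axes)), rep(sqrt(qchisq(0.9, 2)), 2),
               tolerance = 0.08)

  # prediction coverage of a new same-distribution point
  withr::with_seed(14, {
    hits <- replicate(3000, {
      pts <- matrix(rnorm(16), 8, 2) %*% matrix(c(2, 0.5, 0, 1), 2)
      in_ellipse(confidence_ellipse(pts[1:7, ], 0.9), pts[8, ])
    })
  })
  se <- sqrt(0.9 * 0.1 / 3000)
  expect_lt(abs(mean(hits) - 0.9), 3 * se)

  expect_error(confidence_ellipse(matrix(rnorm(4), 2, 2)), "m >= 3")
  degen <- cbind(1:5, 2 * (1:5))
  expect_error(confidence_ellipse(degen), "degenerate")
})
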