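#' Principal component analysis of a Pareto-scaled bin matrix
#'
#' Mean-centered singular value decomposition of the pooled (both brands)
#' matrix: scores are the centered data projected on the loadings, and
#' explained-variance fractions come from the squared singular values.
#'
#' @param matrix a `bin_matrix` at stage `"pareto"`, or a plain numeric
#'   matrix (rows = lots).
#' @param n_components number of components to retain; must satisfy
#'   `n_components <= min(lots - 1, bins)`. Default 3.
#' @return An object of class `pca_model`: `loadings` (bins x p, orthonormal
#'   columns), `scores` (lots x p), `explained_fraction` (length = full rank,
#'   non-increasing, sums to 1), `center`, `lots` (when available).
#' @export
fit_pca <- function(matrix, n_components = 3) {
  if (inherits(matrix, "bin_matrix")) {
    if (matrix$stage != "pareto") {
      stop("fit_pca: expected stage 'pareto', got '", matrix$stage, "'", call. = FALSE)
    }
    X <- matrix$values
    lots <- matrix$lots
  } else {
    X <- as.matrix(matrix)
    lots <- NULL
  }
  n <- nrow(X); b <- ncol(X)
  pmax_ <- min(n - 1L, b)
  if (n_components < 1L || n_components > pmax_) {
    stop(sprintf("fit_pca: n_components must be in 1..%d (lots - 1 = %d, bins = %d)",
                 pmax_, n - 1L, b), call. = FALSE)
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  sv <- svd(Xc, nu = pmax_, nv = pmax_)
  d2 <- sv$d[seq_len(pmax_)]^2
  structure(
    list(loadings = sv$v[, seq_len(n_components), drop = FALSE],
         scores = sv$u[, seq_len(n_components), drop = FALSE] %*%
           diag(sv$d[seq_len(n_components)], n_components),
         explained_fraction = d2 / sum(d2),
         center = center,
         lots = lots),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  p <- ncol(x$scores)
  cat(sprintf("<pca_model> %d lots, %d components; explained: %s\n",
              nrow(x$scores), p,
              paste(sprintf("%.1f%%", 100 * x$explained_fraction[seq_len(p)]),
                    collapse = " ")))
  invisible(x)
}

#' Split PCA scores into the two brand groups
#'
#' Tabulates the per-brand score matrices A (m x p) and B (n x p) with their
#' mean vectors and sample covariance matrices (denominator m - 1 / n - 1),
#' the ingredients of the pooled-covariance Mahalanobis distance.
#'
#' @param pca a `pca_model` carrying lot metadata, or a scores matrix.
#' @param brand_a,brand_b brand labels (reference and comparator).
#' @param brands character vector of per-row brands, required when `pca` is a
#'   plain matrix.
#' @return An object of class `group_scores`: `A`, `B`, `m`, `n`, `p`,
#'   `mean_A`, `mean_B`, `cov_A`, `cov_B`.
#' @export
group_scores <- function(pca, brand_a, brand_b, brands = NULL) {
  if (inherits(pca, "pca_model")) {
    scores <- pca$scores
    if (is.null(brands)) {
      if (is.null(pca$lots)) stop("group_scores: no brand labels available", call. = FALSE)
      brands <- pca$lots$brand
    }
  } else {
    scores <- as.matrix(pca)
    if (is.null(brands)) stop("group_scores: 'brands' required with a plain matrix", call. = FALSE)
  }
  A <- scores[brands == brand_a, , drop = FALSE]
  B <- scores[brands == brand_b, , drop = FALSE]
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("group_scores: each brand needs at least 2 lots", call. = FALSE)
  }
  structure(
    list(A = A, B = B, m = nrow(A), n = nrow(B), p = ncol(A),
         mean_A = colMeans(A), mean_B = colMeans(B),
         cov_A = stats::cov(A), cov_B = stats::cov(B)),
    class = "group_scores")
}

#' Pool the two group covariance matrices
#'
#' Lot-count-weighted average `S = (m * S_A + n * S_B) / (m + n)`. The
#' weighting is by lot counts, not degrees of freedom, so this is not the
#' unbiased pooled estimator; it is the convention used with the 3.3
#' similarity threshold and is kept verbatim.
#'
#' @param g a `group_scores` object.
#' @return The p x p pooled covariance matrix.
#' @export
pool_covariance <- function(g) {
  stopifnot(inherits(g, "group_scores"))
  if (!identical(dim(g$cov_A), dim(g$cov_B))) {
    stop("pool_covariance: covariance shape mismatch", call. = FALSE)
  }
  (g$m * g$cov_A + g$n * g$cov_B) / (g$m + g$n)
}

#' Mahalanobis distance between two brands in PCA score space
#'
#' `D_M = sqrt( (A_bar - B_bar) S^-1 (A_bar - B_bar)' )` with S the
#' lot-count-pooled covariance of [pool_covariance]. Two brands with
#' `D_M` below the threshold (default 3.3, the practically achievable
#' similarity threshold established on marketed insulin products) are
#' declared similar in higher order structure.
#'
#' @param g a `group_scores` object.
#' @param threshold similarity threshold on `D_M`, default 3.3.
#' @param condition_cap maximum admissible condition number of the pooled
#'   covariance (default 1e10); beyond it the solve is refused.
#' @return An object of class `dm_result`: `dm`, `pooled_cov`, `threshold`,
#'   `verdict` (`"similar"` iff `dm < threshold`).
#' @export
mahalanobis_distance <- function(g, threshold = 3.3, condition_cap = 1e10) {
  stopifnot(inherits(g, "group_scores"))
  S <- pool_covariance(g)
  rc <- rcond(S)
  if (!is.finite(rc) || rc < 1 / condition_cap) {
    stop("mahalanobis_distance: pooled covariance is singular or ill-conditioned; ",
         "use fewer components or more lots", call. = FALSE)
  }
  d <- g$mean_A - g$mean_B
  dm <- sqrt(drop(crossprod(d, solve(S, d))))
  structure(
    list(dm = dm, pooled_cov = S, threshold = threshold,
         verdict = if (dm < threshold) "similar" else "not_similar"),
    class = "dm_result")
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf("<dm_result> D_M = %.3f (threshold %.2f) -> %s\n",
              x$dm, x$threshold, x$verdict))
  invisible(x)
}

#' Confidence ellipse for a group of 2D PCA scores
#'
#' Ellipse containing a new same-distribution observation with the given
#' probability, from the group mean and 2D sample covariance. The default
#' small-sample quantile is the Hotelling prediction form
#' `c2 = 2 (m - 1)(m + 1) / (m (m - 2)) * qf(level, 2, m - 2)`,
#' which converges to the chi-square form `qchisq(level, 2)` as m grows;
#' `method = "chisq"` selects the asymptotic form directly.
#'
#' @param scores m x 2 score matrix, m >= 3.
#' @param level coverage probability in (0, 1), default 0.9.
#' @param method `"hotelling"` (default) or `"chisq"`.
#' @return An object of class `score_ellipse`: `center`, `cov`, `c2`
#'   (squared Mahalanobis radius), `semi_axes` (major, minor), `rotation`
#'   (radians of the major axis), `level`, `m`.
#' @export
confidence_ellipse <- function(scores, level = 0.9, method = c("hotelling", "chisq")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  m <- nrow(scores)
  if (ncol(scores) != 2L || m < 3L) {
    stop("confidence_ellipse: need an m x 2 score matrix with m >= 3", call. = FALSE)
  }
  if (!(level > 0 && level < 1)) stop("confidence_ellipse: level must be in (0, 1)", call. = FALSE)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 1e-12 * max(abs(ev$values), 1e-300)) {
    stop("confidence_ellipse: degenerate score covariance", call. = FALSE)
  }
  c2 <- switch(method,
    hotelling = 2 * (m - 1) * (m + 1) / (m * (m - 2)) * stats::qf(level, 2, m - 2),
    chisq = stats::qchisq(level, 2))
  structure(
    list(center = ctr, cov = S, c2 = c2,
         semi_axes = sqrt(ev$values * c2),
         rotation = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
         level = level, m = m, method = method),
    class = "score_ellipse")
}

#' Test points for membership in a score ellipse
#'
#' @param ellipse a `score_ellipse`.
#' @param points numeric vector of length 2 or an n x 2 matrix.
#' @return Logical vector: TRUE where the point lies inside or on the ellipse.
#' @export
in_ellipse <- function(ellipse, points) {
  stopifnot(inherits(ellipse, "score_ellipse"))
  pts <- if (is.null(dim(points))) matrix(points, ncol = 2L) else as.matrix(points)
  d2 <- stats::mahalanobis(pts, ellipse$center, ellipse$cov)
  d2 <= ellipse$c2 + 1e-12
}

#' Full 1D similarity pipeline: spectra to Mahalanobis distance
#'
#' Convenience wrapper chaining [bin_spectra()], [sum_normalize()],
#' [pareto_scale()], [fit_pca()] (on the pooled two-brand matrix),
#' [group_scores()] and [mahalanobis_distance()].
#'
#' @param spectra list of [spectrum1d] for both brands.
#' @param brand_a,brand_b the two brand labels; defaults to the first two
#'   distinct brands found, in order of appearance.
#' @param exclusions an [exclusion_set], default [default_exclusions()].
#' @param bin_width ppm, default 0.01.
#' @param n_components PCA components for the distance, default 3.
#' @param threshold similarity threshold, default 3.3.
#' @return A list: `dm_result`, `pca`, `groups`, `bin_matrix` (pareto stage).
#' @export
dm_pipeline <- function(spectra, brand_a = NULL, brand_b = NULL,
                        exclusions = default_exclusions(), bin_width = 0.01,
                        n_components = 3, threshold = 3.3) {
  bm <- pareto_scale(sum_normalize(bin_spectra(spectra, exclusions, bin_width)))
  pca <- fit_pca(bm, n_components)
  br <- unique(bm$lots$brand)
  if (is.null(brand_a)) brand_a <- br[1]
  if (is.null(brand_b)) brand_b <- setdiff(br, brand_a)[1]
  g <- group_scores(pca, brand_a, brand_b)
  list(dm_result = mahalanobis_distance(g, threshold = threshold),
       pca = pca, groups = g, bin_matrix = bm)
}
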