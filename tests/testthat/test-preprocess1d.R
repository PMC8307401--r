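test_that("binning tiles the window and sums points per half-open bin", {
  # uniform density: 10 bins each collecting 10 unit points
  x <- seq(0, 0.0999, by = 0.001)
  sp <- spectrum1d(x, rep(1, length(x)), brand = "A", lot = "1")
  bm <- bin_spectra(list(sp), exclusion_set(window = c(0, 0.1)), bin_width = 0.01)
  expect_equal(ncol(bm$values), 10L)
  expect_equal(unname(bm$values[1, ]), rep(10, 10))
  expect_identical(bm$stage, "raw_bins")

  # interval arithmetic: (0,1) minus (0.4,0.6) at 0.01 -> 80 bins
  sp2 <- flat_spectrum(c(-0.01, 1.01), 0.001)
  bm2 <- bin_spectra(list(sp2), exclusion_set(rbind(c(0.4, 0.6)), c(0, 1)), 0.01)
  expect_equal(ncol(bm2$values), 80L)
})

test_that("each bin equals the brute-force point-loop oracle", {
  withr::with_seed(42, {
    sp <- random_spectrum(c(-0.1, 1.1), n = 3000)
  })
  excl <- exclusion_set(rbind(c(0.2, 0.35), c(0.7, 0.75)), window = c(0, 1))
  bm <- bin_spectra(list(sp), excl, 0.05)
  expect_equal(unname(bm$values[1, ]),
               oracle_bin(sp, bm$bin_edges[, 1], bm$bin_edges[, 2]))
  # conservation: row total equals total intensity over included points
  incl <- rep(FALSE, length(sp$ppm))
  for (k in seq_len(nrow(bm$bin_edges))) {
    incl <- incl | (sp$ppm >= bm$bin_edges[k, 1] & sp$ppm < bm$bin_edges[k, 2])
  }
  expect_equal(sum(bm$values[1, ]), sum(sp$intensity[incl]))
  # exclusion correctness: no bin overlaps an exclusion interval
  for (k in seq_len(nrow(excl$intervals))) {
    ov <- pmin(bm$bin_edges[, 2], excl$intervals[k, 2]) -
      pmax(bm$bin_edges[, 1], excl$intervals[k, 1])
    expect_true(all(ov <= 1e-9))
  }
})

test_that("default exclusions reproduce the 370-bin layout at 0.01 ppm", {
  bm <- bin_spectra(list(flat_spectrum()), default_exclusions(), 0.01)
  expect_equal(ncol(bm$values), 370L)
  # the 8.45-8.47 region lies outside the (0, 8) window
  expect_equal(max(bm$bin_edges), 8)
})

test_that("coverage and empty-bin violations are reported with lot names", {
  short <- flat_spectrum(c(0.5, 8.2), brand = "A", lot = "short")
  expect_error(bin_spectra(list(short), default_exclusions(), 0.01), "short")
  sparse <- spectrum1d(seq(-0.1, 1.1, by = 0.05), rep(1, 25), brand = "A", lot = "sp")
  expect_error(bin_spectra(list(sparse), exclusion_set(window = c(0, 1)), 0.01),
               "coarser")
})

test_that("integrity check names failing lots and bins", {
  sp <- flat_spectrum(c(-0.05, 1.05), 0.001, brand = "A", lot = "L1")
  bm <- bin_spectra(list(sp, flat_spectrum(c(-0.05, 1.05), 0.001, brand = "B", lot = "L2")),
                    exclusion_set(window = c(0, 1)), 0.1)
  rep <- integrity_check(bm)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$n_nonfinite, c(0L, 0L))

  bad <- bm; bad$values[2, 3] <- NaN
  expect_error(integrity_check(bad), "L2")
  neg <- bm; neg$values[1, ] <- -neg$values[1, ]
  expect_error(integrity_check(neg), "non-positive.*L1|L1.*non-positive")
})

test_that("sum normalization scales rows to 100 and is scale invariant", {
  sp1 <- flat_spectrum(c(-0.05, 1.05), 0.001, brand = "A", lot = "1")
  sp2 <- sp1; sp2$intensity <- 7 * sp2$intensity; sp2$lot <- "2"
  bm <- sum_normalize(bin_spectra(list(sp1, sp2), exclusion_set(window = c(0, 1)), 0.1))
  expect_identical(bm$stage, "normalized")
  expect_equal(rowSums(bm$values), c(100, 100), tolerance = 1e-12)
  expect_equal(bm$values[1, ], bm$values[2, ], tolerance = 1e-12)

  # closed form on a tiny hand matrix
  hand <- hosnmr:::new_bin_matrix(matrix(c(1, 1, 2), 1), cbind(0:2, 1:3),
                                  data.frame(brand = "A", lot = "1"), "raw_bins")
  expect_equal(unname(sum_normalize(hand)$values[1, ]), c(25, 25, 50))
})

test_that("Pareto scaling matches the closed form and its variance identity", {
  mk <- function(v, stage = "normalized") {
    hosnmr:::new_bin_matrix(v, cbind(seq_len(ncol(v)) - 1, seq_len(ncol(v))),
                            data.frame(brand = "A", lot = as.character(seq_len(nrow(v)))),
                            stage)
  }
  ps <- pareto_scale(mk(matrix(c(1, 3), 2, 1)))
  expect_identical(ps$stage, "pareto")
  expect_equal(unname(ps$values[, 1]), c(-1, 1) / 2^0.25, tolerance = 1e-12)

  expect_warning(cz <- pareto_scale(mk(matrix(c(5, 5, 5, 1, 2, 3), 3, 2))), "constant")
  expect_equal(unname(cz$values[, 1]), c(0, 0, 0))

  withr::with_seed(9, { m <- matrix(rexp(60), 5, 12) })
  pre_sd <- apply(m, 2, sd)
  out <- pareto_scale(mk(m))
  expect_equal(unname(apply(out$values, 2, var)), unname(pre_sd), tolerance = 1e-9)
})

test_that("stage transitions are enforced", {
  sp <- flat_spectrum(c(-0.05, 1.05), 0.001)
  raw <- bin_spectra(list(sp, flat_spectrum(c(-0.05, 1.05), 0.001, lot = "2")),
                     exclusion_set(window = c(0, 1)), 0.1)
  norm <- sum_normalize(raw)
  expect_error(sum_normalize(norm), "raw_bins")
  expect_error(pareto_scale(raw), "normalized")
  par <- suppressWarnings(pareto_scale(norm))  # identical flat lots: all-constant columns
  expect_error(pareto_scale(par), "normalized")
  expect_error(integrity_check(par), "raw_bins")
  one_row <- hosnmr:::new_bin_matrix(matrix(1:3, 1), cbind(0:2, 1:3),
                                     data.frame(brand = "A", lot = "1"), "normalized")
  expect_error(pareto_scale(one_row), "2 lots")
})
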