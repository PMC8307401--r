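fixture <- glargine_methyl_profile()

test_that("peak matching handles identity, jitter, and missing peaks", {
  base <- mk_peaks(paste0("p", 1:5), seq(0.3, 1.1, 0.2), seq(14, 26, 3),
                   c(5, 4, 3, 2, 1) * 1e6)
  lists <- list(base,
                mk_peaks(paste0("p", 1:5), base$proton_shift, base$hetero_shift,
                         base$height, brand = "A", lot = "2"),
                mk_peaks(paste0("p", 1:5), base$proton_shift, base$hetero_shift,
                         base$height, brand = "B", lot = "1"),
                mk_peaks(paste0("p", 1:5), base$proton_shift, base$hetero_shift,
                         base$height, brand = "B", lot = "2"))
  ps <- match_peaks(lists)
  expect_s3_class(ps, "peak_set")
  expect_equal(length(attr(ps, "complete_labels")), 5L)
  expect_equal(nrow(ps), 20L)

  # unlabeled geometric matching under jitter well below tolerance
  s <- peaklist_scenario(n_peaks = 48, seed = 3)   # 1 ppb 1H / 5 ppb 13C jitter
  sim <- simulate_peaklists(s, 2, 2)
  unlab <- lapply(sim$lists, function(l) {
    l$label <- paste0("x", seq_len(nrow(l)))       # break label identity
    hosnmr:::as_peaklist(l, attr(l, "brand"), attr(l, "lot"))
  })
  ps48 <- match_peaks(unlab)
  expect_equal(length(attr(ps48, "complete_labels")), 48L)
  # geometric match agrees with generator ground truth (same row order)
  first <- ps48[ps48$brand == "A" & ps48$lot == "A01", ]
  expect_equal(first$height, sim$lists[[1]]$height)

  # one lot missing one peak -> that set incomplete, 4 of 5 complete
  drop1 <- lists
  drop1[[3]] <- hosnmr:::as_peaklist(lists[[3]][-2, ], "B", "1")
  expect_message(ps4 <- match_peaks(drop1), "incomplete")
  expect_equal(length(attr(ps4, "complete_labels")), 4L)
  expect_equal(attr(ps4, "incomplete_labels"), "p2")
})

test_that("mean shifts are per-brand arithmetic means", {
  ps <- match_peaks(list(
    mk_peaks("p1", 1.000, 20.0, 1, brand = "A", lot = "1"),
    mk_peaks("p1", 1.002, 20.4, 1, brand = "A", lot = "2"),
    mk_peaks("p1", 1.001, 20.2, 1, brand = "B", lot = "1"),
    mk_peaks("p1", 1.003, 20.6, 1, brand = "B", lot = "2")))
  expect_equal(unname(mean_shifts(ps, "A")), c(1.001, 20.2))
  withr::with_seed(21, {
    h <- runif(6, 0.2, 1.4); x <- runif(6, 12, 27)
    lists <- lapply(1:6, function(i)
      mk_peaks("q", h[i], x[i], 1, brand = if (i <= 3) "A" else "B", lot = as.character(i)))
  })
  ps2 <- match_peaks(lists, tol_h = 2, tol_x = 20)
  expect_equal(unname(mean_shifts(ps2, "A")), c(sum(h[1:3]) / 3, sum(x[1:3]) / 3))
})

test_that("shift differences classify against the ppb metrics", {
  mk_ps <- function(dh_ppb, dx_ppb) match_peaks(list(
    mk_peaks("p1", 1.0, 20.0, 1, brand = "A", lot = "1"),
    mk_peaks("p1", 1.0, 20.0, 1, brand = "A", lot = "2"),
    mk_peaks("p1", 1.0 + dh_ppb / 1000, 20.0 + dx_ppb / 1000, 1, brand = "B", lot = "1"),
    mk_peaks("p1", 1.0 + dh_ppb / 1000, 20.0 + dx_ppb / 1000, 1, brand = "B", lot = "2")),
    tol_h = 1, tol_x = 1)

  zero <- shift_difference(mk_ps(0, 0), "A", "B")
  expect_equal(c(zero$delta_h, zero$delta_x), c(0, 0))
  expect_true(zero$within_metric)

  # the observed between-brand maxima sit inside the rounded 4/15 ppb metrics
  obs <- shift_difference(mk_ps(3.4, -13), "A", "B")
  expect_equal(obs$delta_h, 3.4, tolerance = 1e-9)
  expect_equal(obs$delta_x, -13, tolerance = 1e-9)
  expect_true(obs$within_metric)
  expect_false(shift_difference(mk_ps(4.5, 0), "A", "B")$within_metric)

  # antisymmetry under brand exchange
  fwd <- shift_difference(mk_ps(2.5, -8), "A", "B")
  rev <- shift_difference(mk_ps(2.5, -8), "B", "A")
  expect_equal(rev$delta_h, -fwd$delta_h, tolerance = 1e-12)
  expect_equal(rev$delta_x, -fwd$delta_x, tolerance = 1e-12)
})

test_that("relative intensities normalize per lot and are scale invariant", {
  lists <- list(
    mk_peaks(c("ref", "a"), c(1, 0.5), c(20, 15), c(200, 50), brand = "A", lot = "1"),
    mk_peaks(c("ref", "a"), c(1, 0.5), c(20, 15), c(400, 100), brand = "A", lot = "2"),
    mk_peaks(c("ref", "a"), c(1, 0.5), c(20, 15), c(100, 30), brand = "B", lot = "1"),
    mk_peaks(c("ref", "a"), c(1, 0.5), c(20, 15), c(300, 90), brand = "B", lot = "2"))
  ps <- match_peaks(lists)
  ri <- relative_intensities(ps, "ref")
  expect_equal(ri$rel_int[ri$peak_label == "ref"], rep(100, 4))
  expect_equal(ri$rel_int[ri$peak_label == "a" & ri$lot == "1" & ri$brand == "A"], 25)

  # per-lot uniform rescaling leaves every relative intensity unchanged
  scaled <- lapply(seq_along(lists), function(i) {
    l <- lists[[i]]; l$height <- l$height * c(3, 0.1, 7, 11)[i]
    hosnmr:::as_peaklist(l, attr(l, "brand"), attr(l, "lot"))
  })
  ri2 <- relative_intensities(match_peaks(scaled), "ref")
  expect_equal(ri2$rel_int, ri$rel_int, tolerance = 1e-12)

  noref <- match_peaks(lists)
  noref <- noref[!(noref$peak_label == "ref" & noref$lot == "2" & noref$brand == "B"), ]
  expect_error(relative_intensities(noref, "ref"), "B/2")
})

test_that("welch_test follows the Welch form and degenerate conventions", {
  expect_equal(welch_test(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_message(p0 <- welch_test(c(2, 2), c(3, 3)), "zero variance")
  expect_equal(p0, 0)
  expect_message(p1 <- welch_test(c(2, 2), c(2, 2)), "zero variance")
  expect_equal(p1, 1)
  expect_error(welch_test(1, c(1, 2)), "at least 2")

  withr::with_seed(61, {
    for (r in 1:10) {
      a <- rnorm(5); b <- rnorm(6, 0.5)
      p <- welch_test(a, b)
      expect_equal(welch_test(b, a), p, tolerance = 1e-12)          # symmetry
      expect_equal(welch_test(3 * a - 2, 3 * b - 2), p, tolerance = 1e-9)  # affine
    }
  })
})

test_that("welch_test ranks agree with the exhaustive permutation oracle", {
  # Welch p and the exhaustive studentized permutation p differ systematically
  # at n = 5 (see the methods vignette); their orderings must still agree.
  withr::with_seed(62, {
    pairs <- replicate(15, {
      a <- rnorm(5, 10, 2); b <- rnorm(5, 10 + sample(c(0, 1.5, 3), 1), 2)
      c(welch_test(a, b), perm_pvalue_exact(a, b))
    })
  })
  expect_gt(cor(pairs[1, ], pairs[2, ], method = "spearman"), 0.95)
})

test_that("the packaged glargine table reproduces the published profile", {
  cmp <- compare_intensities(fixture$relint, fixture$brand_a, fixture$brand_b,
                             fixture$reference_label)
  expect_equal(nrow(cmp), 48L)
  expect_true(is.na(cmp$p_value[cmp$peak_label == "Thr-d"]))

  # recomputed p agrees with the printed column within the quantization bound
  # of the shipped intensities (printed at 0.1), and classifies identically
  printed <- fixture$p_printed[cmp$peak_label]
  testable <- !is.na(printed)
  expect_equal(sum(testable), 47L)
  expect_lt(max(abs(cmp$p_value[testable] - printed[testable])), 0.031)
  expect_identical(cmp$p_value[testable] < 0.05, unname(printed[testable] < 0.05))
  expect_equal(cmp$peak_label[!is.na(cmp$p_value) & cmp$p_value < 0.05], "Leu-t")

  eq <- equivalence_summary(cmp)
  expect_equal(eq$equivalent, 47L)
  expect_equal(eq$total, 48L)
  expect_equal(eq$fraction_rounded, 98)
  expect_equal(eq$excluding_reference$equivalent, 46L)
  expect_equal(eq$excluding_reference$total, 47L)
})

test_that("equivalence summary boundary behaviour", {
  cmp <- data.frame(peak_label = c("r", "a", "b"), mean_A = 1, sd_A = 1,
                    mean_B = 1, sd_B = 1, p_value = c(NA, 0.5, 0.5),
                    equivalent = c(NA, TRUE, TRUE))
  expect_equal(equivalence_summary(cmp)$fraction, 100)
  expect_equal(equivalence_summary(cmp, alpha = 0)$equivalent, 3L)
  cmp$p_value <- c(NA, 0.01, 0.5)
  expect_equal(equivalence_summary(cmp)$equivalent, 2L)
  expect_error(equivalence_summary(cmp[0, ]), "empty")
})
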