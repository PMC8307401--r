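#' Excipient/solvent exclusion set
#'
#' Defines the overall analysis window and the ppm regions excluded from
#' binning (excipient, residual-solvent, water and blank regions). Intervals
#' are given as (low, high) ppm pairs regardless of axis direction; they are
#' clipped to the window and overlapping intervals are merged.
#'
#' @param intervals numeric matrix or list of length-2 vectors, each
#'   `(low, high)` in ppm with `low < high`. May be empty.
#' @param window length-2 numeric `(low, high)` analysis window in ppm.
#' @return An object of class `exclusion_set` with elements `intervals`
#'   (two-column matrix, merged and clipped) and `window`.
#' @seealso [default_exclusions()] for the mAb drug-product defaults.
#' @export
exclusion_set <- function(intervals = NULL, window = c(0, 8)) {
  window <- as.numeric(window)
  if (length(window) != 2L || !(window[1] < window[2])) {
    stop("exclusion_set: window must be (low, high) with low < high", call. = FALSE)
  }
  if (is.null(intervals) || !length(intervals)) {
    iv <- matrix(numeric(0), ncol = 2L)
  } else {
    if (is.list(intervals)) intervals <- do.call(rbind, intervals)
    iv <- matrix(as.numeric(intervals), ncol = 2L)
    if (any(iv[, 1] >= iv[, 2])) {
      stop("exclusion_set: each interval needs low < high", call. = FALSE)
    }
    # clip to window, drop empty, merge overlaps
    iv[, 1] <- pmax(iv[, 1], window[1])
    iv[, 2] <- pmin(iv[, 2], window[2])
    iv <- iv[iv[, 1] < iv[, 2], , drop = FALSE]
    if (nrow(iv) > 1L) {
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      merged <- iv[1, , drop = FALSE]
      for (k in seq_len(nrow(iv))[-1]) {
        last <- nrow(merged)
        if (iv[k, 1] <= merged[last, 2]) {
          merged[last, 2] <- max(merged[last, 2], iv[k, 2])
        } else {
          merged <- rbind(merged, iv[k, ])
        }
      }
      iv <- merged
    }
  }
  colnames(iv) <- c("low", "high")
  structure(list(intervals = iv, window = window), class = "exclusion_set")
}

#' Default exclusion regions for formulated mAb drug products
#'
#' The eight regions covering excipient, residual solvent, water and blank
#' signals: 0-0.2, 0.85-0.95, 1.15-1.45, 1.55-1.65, 1.9-2.1, 2.2-2.9, 3.3-6
#' and 8.45-8.47 ppm, inside a (0, 8) ppm analysis window. With 0.01 ppm bins
#' this leaves 370 bins (the 8.45-8.47 region lies outside the default
#' window). The window is a reconstruction and can be overridden.
#'
#' @param window analysis window, default `c(0, 8)` ppm.
#' @return An [exclusion_set].
#' @export
default_exclusions <- function(window = c(0, 8)) {
  exclusion_set(
    intervals = rbind(c(0, 0.2), c(0.85, 0.95), c(1.15, 1.45), c(1.55, 1.65),
                      c(1.9, 2.1), c(2.2, 2.9), c(3.3, 6), c(8.45, 8.47)),
    window = window)
}

new_bin_matrix <- function(values, bin_edges, lots, stage) {
  structure(list(values = values, bin_edges = bin_edges, lots = lots, stage = stage),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat(sprintf("<bin_matrix> %d lots x %d bins, width %.4g ppm, stage '%s'\n",
              nrow(x$values), ncol(x$values),
              x$bin_edges[1, 2] - x$bin_edges[1, 1], x$stage))
  invisible(x)
}

#' Bin a set of 1D spectra into a lots-by-bins matrix
#'
#' Tiles the analysis window with half-open fixed-width bins `[low, high)`
#' starting at the window's low edge, drops every bin that overlaps an
#' exclusion interval, and sums the intensities of the data points falling in
#' each surviving bin. All spectra must cover the analysis window.
#'
#' Bin edges are computed in exact decimal steps (rounded to the nearest
#' 1e-6 ppm) so floating drift cannot change the bin count.
#'
#' @param spectra list of [spectrum1d] objects.
#' @param exclusions an [exclusion_set]; default [default_exclusions()].
#' @param bin_width bin width in ppm, default 0.01.
#' @return A `bin_matrix` at stage `"raw_bins"`: `values` (lots x bins),
#'   `bin_edges` (two-column low/high matrix), `lots` (data.frame with
#'   `brand`, `lot`), `stage`.
#' @export
bin_spectra <- function(spectra, exclusions = default_exclusions(), bin_width = 0.01) {
  stopifnot(length(spectra) >= 1L, bin_width > 0)
  if (inherits(spectra, "spectrum1d")) spectra <- list(spectra)
  win <- exclusions$window
  n_bins_total <- floor((win[2] - win[1]) / bin_width + 1e-9)
  if (n_bins_total < 1L) stop("bin_spectra: window narrower than one bin", call. = FALSE)
  edges <- round(win[1] + bin_width * (0:n_bins_total), 6L)
  lows <- edges[-length(edges)]
  highs <- edges[-1L]
  keep <- rep(TRUE, n_bins_total)
  for (k in seq_len(nrow(exclusions$intervals))) {
    iv <- exclusions$intervals[k, ]
    # positive-measure overlap with the exclusion interval
    keep <- keep & !(pmin(highs, iv[2]) - pmax(lows, iv[1]) > 1e-9)
  }
  if (!any(keep)) stop("bin_spectra: exclusions remove every bin", call. = FALSE)
  kept_low <- lows[keep]
  kept_high <- highs[keep]

  vals <- matrix(NA_real_, nrow = length(spectra), ncol = sum(keep))
  lots <- data.frame(brand = character(length(spectra)),
                     lot = character(length(spectra)), stringsAsFactors = FALSE)
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    stopifnot(inherits(sp, "spectrum1d"))
    lots$brand[i] <- sp$brand; lots$lot[i] <- sp$lot
    pp <- rev(sp$ppm)            # ascending for findInterval
    it <- rev(sp$intensity)
    if (min(pp) > win[1] + 1e-9 || max(pp) < win[2] - bin_width) {
      stop(sprintf("bin_spectra: spectrum %s/%s (%.3f..%.3f ppm) does not cover the window (%g, %g)",
                   sp$brand, sp$lot, min(pp), max(pp), win[1], win[2]), call. = FALSE)
    }
    idx <- findInterval(pp, edges, left.open = FALSE, rightmost.closed = FALSE)
    inw <- idx >= 1L & idx <= n_bins_total
    sums <- numeric(n_bins_total)
    agg <- rowsum(it[inw], idx[inw])
    sums[as.integer(rownames(agg))] <- agg[, 1]
    counts <- tabulate(idx[inw], nbins = n_bins_total)
    if (any(counts[keep] == 0L)) {
      b <- which(keep)[which(counts[keep] == 0L)[1]]
      stop(sprintf("bin_spectra: bin [%g, %g) holds no data points for lot %s/%s; use coarser bins",
                   lows[b], highs[b], sp$brand, sp$lot), call. = FALSE)
    }
    vals[i, ] <- sums[keep]
  }
  colnames(vals) <- sprintf("%.6g", (kept_low + kept_high) / 2)
  new_bin_matrix(vals, cbind(low = kept_low, high = kept_high), lots, "raw_bins")
}

#' Integrity check on a raw bin matrix
#'
#' Verifies that every cell is finite and every lot's total intensity is
#' positive (sum normalization divides by the total). Failing lots are named.
#'
#' @param matrix a `bin_matrix` at stage `"raw_bins"`.
#' @return Invisibly, a data.frame with one row per lot: `brand`, `lot`,
#'   `total`, `n_nonfinite`. Errors on any violation.
#' @export
integrity_check <- function(matrix) {
  stopifnot(inherits(matrix, "bin_matrix"))
  if (matrix$stage != "raw_bins") {
    stop("integrity_check: expected stage 'raw_bins', got '", matrix$stage, "'", call. = FALSE)
  }
  nonfin <- !is.finite(matrix$values)
  rep <- data.frame(matrix$lots,
                    total = rowSums(ifelse(nonfin, 0, matrix$values)),
                    n_nonfinite = rowSums(nonfin))
  if (any(nonfin)) {
    ij <- which(nonfin, arr.ind = TRUE)[1, ]
    stop(sprintf("integrity_check: non-finite cell for lot %s/%s in bin [%g, %g)",
                 matrix$lots$brand[ij[1]], matrix$lots$lot[ij[1]],
                 matrix$bin_edges[ij[2], 1], matrix$bin_edges[ij[2], 2]), call. = FALSE)
  }
  if (any(rep$total <= 0)) {
    bad <- which(rep$total <= 0)[1]
    stop(sprintf("integrity_check: lot %s/%s has non-positive total intensity (%g)",
                 rep$brand[bad], rep$lot[bad], rep$total[bad]), call. = FALSE)
  }
  invisible(rep)
}

#' Sum-normalize a bin matrix
#'
#' Divides each lot's row by its own total intensity and rescales to a
#' constant row sum of 100, so lots are comparable despite assay or receiver
#' gain differences.
#'
#' @param matrix a `bin_matrix` at stage `"raw_bins"`.
#' @return The matrix at stage `"normalized"` (row sums = 100).
#' @export
sum_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "bin_matrix"))
  if (matrix$stage != "raw_bins") {
    stop("sum_normalize: expected stage 'raw_bins', got '", matrix$stage, "'", call. = FALSE)
  }
  integrity_check(matrix)
  matrix$values <- 100 * matrix$values / rowSums(matrix$values)
  matrix$stage <- "normalized"
  matrix
}

#' Pareto-scale a normalized bin matrix
#'
#' Column-wise transform `x -> (x - mean(x)) / sqrt(sd(x))` with the sample
#' standard deviation (denominator n - 1). Pareto scaling down-weights
#' intense bins less aggressively than unit-variance scaling, the usual
#' compromise for spectral chemometrics. Columns with zero standard deviation
#' are centered (to zero) and left undivided, with a warning.
#'
#' @param matrix a `bin_matrix` at stage `"normalized"` with >= 2 rows.
#' @return The matrix at stage `"pareto"`.
#' @export
pareto_scale <- function(matrix) {
  stopifnot(inherits(matrix, "bin_matrix"))
  if (matrix$stage != "normalized") {
    stop("pareto_scale: expected stage 'normalized', got '", matrix$stage, "'", call. = FALSE)
  }
  if (nrow(matrix$values) < 2L) {
    stop("pareto_scale: at least 2 lots required (no variance defined)", call. = FALSE)
  }
  mu <- colMeans(matrix$values)
  sdev <- apply(matrix$values, 2L, stats::sd)
  zero <- sdev == 0
  if (any(zero)) {
    warning(sprintf("pareto_scale: %d constant column(s) centered but not scaled", sum(zero)))
  }
  denom <- ifelse(zero, 1, sqrt(sdev))
  matrix$values <- sweep(sweep(matrix$values, 2L, mu, "-"), 2L, denom, "/")
  matrix$stage <- "pareto"
  matrix
}

#' Export a bin matrix as delimited text
#'
#' Writes a TSV with a `brand`, `lot` column pair and one column per bin,
#' headed by the bin-center ppm value.
#'
#' @param matrix a `bin_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bin_matrix <- function(matrix, path) {
  centers <- (matrix$bin_edges[, 1] + matrix$bin_edges[, 2]) / 2
  df <- data.frame(matrix$lots, matrix$values, check.names = FALSE)
  names(df) <- c("brand", "lot", sprintf("%.6g", centers))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
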