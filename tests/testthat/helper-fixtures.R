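# Shared in-code fixtures for the test suite.

write_xy <- function(ppm, intensity, path = tempfile(fileext = ".txt")) {
  writeLines(paste(format(ppm, digits = 17, trim = TRUE, scientific = FALSE),
                   format(intensity, digits = 17, trim = TRUE)), path)
  path
}

# flat unit-intensity spectrum sampled every `dppm` across `range`
flat_spectrum <- function(range = c(-0.05, 8.2), dppm = 0.001, value = 1,
                          brand = "A", lot = "1") {
  x <- seq(range[1], range[2], by = dppm)
  spectrum1d(x, rep(value, length(x)), brand = brand, lot = lot)
}

# irregular random spectrum covering `range` (fixed draw under current seed)
random_spectrum <- function(range = c(-0.1, 1.1), n = 2000, brand = "A", lot = "1") {
  x <- sort(runif(n, range[1], range[2]))
  x <- x[c(TRUE, diff(x) > 0)]           # strictly monotonic
  spectrum1d(x, rexp(length(x)), brand = brand, lot = lot)
}

# brute-force binning oracle: loop over points, low <= ppm < high
oracle_bin <- function(sp, lows, highs) {
  vapply(seq_along(lows), function(k)
    sum(sp$intensity[sp$ppm >= lows[k] & sp$ppm < highs[k]]), 0.0)
}

# plain peak list data frame helper
mk_peaks <- function(labels, h, x, height, snr = NA_real_,
                     brand = "A", lot = "1") {
  hosnmr:::as_peaklist(
    data.frame(label = labels, proton_shift = h, hetero_shift = x,
               height = height, snr = snr, stringsAsFactors = FALSE),
    brand, lot)
}

# studentized Monte-Carlo permutation p-value (independent Welch oracle)
perm_pvalue <- function(a, b, B = 2000) {
  z <- c(a, b); na <- length(a)
  stat <- function(ix) {
    x <- z[ix]; y <- z[-ix]
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  tobs <- abs(stat(seq_len(na)))
  tp <- replicate(B, abs(stat(sample(length(z), na))))
  mean(tp >= tobs - 1e-12)
}

# exhaustive permutation p-value for 5 v 5 samples
perm_pvalue_exact <- function(a, b) {
  z <- c(a, b); n <- length(a)
  stat <- function(ix) {
    x <- z[ix]; y <- z[-ix]
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  tobs <- abs(stat(seq_len(n)))
  cmb <- utils::combn(length(z), n)
  tp <- apply(cmb, 2, function(ix) abs(stat(ix)))
  mean(tp >= tobs - 1e-12)
}

expect_same_spectrum <- function(a, b) {
  expect_identical(a$ppm, b$ppm)
  expect_identical(a$intensity, b$intensity)
}
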