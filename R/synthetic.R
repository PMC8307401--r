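# Deterministic substreams: one master seed; each (brand, lot) draws from an
# independent stream keyed by a string hash, so adding a lot never perturbs
# the draws of existing lots.
substream_seed <- function(seed, key) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, key))
  expr
}

lorentzian <- function(x, center, width, amplitude) {
  hw2 <- (width / 2)^2
  amplitude * hw2 / ((x - center)^2 + hw2)
}

#' Scenario for synthetic formulated-drug-product 1D spectra
#'
#' Emulates the qualitative structure of a protein drug product 1D 1H
#' spectrum: a few strong, sharp excipient peaks, many weak, broad protein
#' peaks, Gaussian noise, and lot-to-lot shift/intensity jitter. Lorentzian
#' lineshapes throughout (the natural NMR lineshape; `lineshape = "gaussian"`
#' available). Default excipient peaks sit inside the standard exclusion
#' regions and default protein peaks outside them, with a 100:1
#' excipient-to-protein amplitude ratio and protein linewidths 15-40 times
#' the excipient linewidths.
#'
#' @param window simulated ppm range (wider than the (0, 8) analysis window).
#' @param point_spacing grid spacing in ppm (default 0.002).
#' @param excipient_peaks,protein_peaks data.frames with columns `center`,
#'   `width`, `amplitude` (ppm, ppm, arbitrary units).
#' @param noise_sd per-point Gaussian noise standard deviation.
#' @param lot_jitter `c(shift_sd, amp_rel_sd)`: per-peak, per-lot chemical
#'   shift jitter (ppm) and relative amplitude jitter.
#' @param brand_effect optional injected brand difference: a list with
#'   `brand`, `peak_index` (row of `protein_peaks`), `shift` (ppm offset) and
#'   `amp_factor`, applied only to that brand's lots.
#' @param seed master seed (integer).
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @return A `spectrum_scenario` list.
#' @export
spectrum_scenario <- function(window = c(-0.5, 8.5), point_spacing = 0.002,
                              excipient_peaks = NULL, protein_peaks = NULL,
                              noise_sd = 0.02,
                              lot_jitter = c(shift_sd = 0.002, amp_rel_sd = 0.02),
                              brand_effect = NULL, seed = 1L,
                              lineshape = c("lorentzian", "gaussian")) {
  if (is.null(excipient_peaks)) {
    excipient_peaks <- data.frame(
      center = c(0.10, 1.30, 2.00, 2.35, 2.55, 3.70, 4.80, 5.20),
      width = c(0.003, 0.003, 0.003, 0.003, 0.003, 0.004, 0.010, 0.003),
      amplitude = c(60, 100, 80, 60, 50, 120, 200, 30))
  }
  if (is.null(protein_peaks)) {
    protein_peaks <- data.frame(
      center = c(0.35, 0.55, 0.75, 1.00, 1.05, 1.50, 1.70, 1.80,
                 3.00, 3.15, 6.40, 6.70, 7.00, 7.30, 7.60, 7.90),
      width = c(0.08, 0.10, 0.08, 0.06, 0.06, 0.05, 0.08, 0.07,
                0.06, 0.06, 0.08, 0.09, 0.08, 0.09, 0.08, 0.08),
      amplitude = c(1.2, 1.0, 0.9, 1.1, 0.8, 0.7, 0.9, 0.8,
                    0.6, 0.7, 0.5, 0.6, 0.8, 0.9, 0.7, 0.5))
  }
  stopifnot(all(excipient_peaks$width > 0), all(protein_peaks$width > 0),
            all(excipient_peaks$amplitude >= 0), all(protein_peaks$amplitude >= 0),
            point_spacing > 0, window[1] < window[2])
  structure(
    list(window = as.numeric(window), point_spacing = point_spacing,
         excipient_peaks = excipient_peaks, protein_peaks = protein_peaks,
         noise_sd = noise_sd,
         lot_jitter = c(shift_sd = unname(lot_jitter[1]),
                        amp_rel_sd = unname(lot_jitter[2])),
         brand_effect = brand_effect, seed = as.integer(seed),
         lineshape = match.arg(lineshape)),
    class = "spectrum_scenario")
}

scenario_peak_table <- function(s, brand) {
  tag <- function(df, kind) {
    if (!nrow(df)) return(cbind(df, kind = character(0)))
    cbind(df, kind = kind)
  }
  pk <- rbind(tag(s$excipient_peaks, "excipient"),
              tag(s$protein_peaks, "protein"))
  be <- s$brand_effect
  if (!is.null(be) && identical(brand, be$brand)) {
    i <- nrow(s$excipient_peaks) + be$peak_index
    pk$center[i] <- pk$center[i] + be$shift
    if (!is.null(be$amp_factor)) pk$amplitude[i] <- pk$amplitude[i] * be$amp_factor
  }
  pk
}

#' Simulate one lot's 1D spectrum
#'
#' Sum of Lorentzian (or Gaussian) lines plus Gaussian noise, with per-peak
#' shift and amplitude jitter drawn from the (seed, brand, lot) substream, so
#' the output is fully reproducible and independent across lots. Any
#' configured brand effect is applied only to the designated brand.
#'
#' @param s a [spectrum_scenario].
#' @param brand,lot labels for the simulated lot.
#' @return A [spectrum1d].
#' @export
simulate_spectrum <- function(s, brand, lot) {
  stopifnot(inherits(s, "spectrum_scenario"))
  x <- seq(s$window[1], s$window[2], by = s$point_spacing)
  pk <- scenario_peak_table(s, brand)
  with_substream(s$seed, paste("spec", brand, lot, sep = "/"), {
    k <- nrow(pk)
    centers <- pk$center + stats::rnorm(k, 0, s$lot_jitter[["shift_sd"]])
    amps <- pk$amplitude * (1 + stats::rnorm(k, 0, s$lot_jitter[["amp_rel_sd"]]))
    amps <- pmax(amps, 0)
    y <- numeric(length(x))
    for (i in seq_len(k)) {
      y <- y + if (s$lineshape == "lorentzian") {
        lorentzian(x, centers[i], pk$width[i], amps[i])
      } else {
        amps[i] * exp(-4 * log(2) * (x - centers[i])^2 / pk$width[i]^2)
      }
    }
    if (s$noise_sd > 0) y <- y + stats::rnorm(length(x), 0, s$noise_sd)
    spectrum1d(x, y, brand = brand, lot = lot)
  })
}

#' Simulate a two-brand lot study of 1D spectra
#'
#' Brand A lots carry no brand effect; brand B lots carry the scenario's
#' configured effect (if any). A ground-truth record of the injected effect
#' accompanies the spectra.
#'
#' @param s a [spectrum_scenario].
#' @param m,n lot counts for brands A and B (each >= 2).
#' @param brand_a,brand_b brand labels, defaults `"A"` and `"B"`.
#' @return List: `spectra` (length m + n, brand A first), `manifest`
#'   (data.frame `brand`, `lot`), `truth` (injected effect or NULL).
#' @export
simulate_group_study <- function(s, m = 7, n = 3, brand_a = "A", brand_b = "B") {
  stopifnot(inherits(s, "spectrum_scenario"), m >= 2, n >= 2)
  be <- s$brand_effect
  if (!is.null(be)) be$brand <- brand_b
  s$brand_effect <- be
  manifest <- data.frame(
    brand = c(rep(brand_a, m), rep(brand_b, n)),
    lot = c(sprintf("%s%02d", brand_a, seq_len(m)), sprintf("%s%02d", brand_b, seq_len(n))),
    stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(nrow(manifest)), function(i)
    simulate_spectrum(s, manifest$brand[i], manifest$lot[i]))
  list(spectra = spectra, manifest = manifest, truth = be)
}

#' Fraction of excipient line intensity removed by an exclusion set
#'
#' Construction bookkeeping for the synthetic scenario: using the analytic
#' Lorentzian integral, computes which fraction of the total excipient
#' intensity inside the analysis window falls in excluded regions. With the
#' default scenario and default exclusions this exceeds 99%.
#'
#' @param s a [spectrum_scenario] (Lorentzian lineshape).
#' @param exclusions an [exclusion_set].
#' @return Fraction in \[0, 1\].
#' @export
excipient_exclusion_fraction <- function(s, exclusions = default_exclusions()) {
  stopifnot(inherits(s, "spectrum_scenario"), s$lineshape == "lorentzian")
  # integral of A * (w/2)^2 / ((x-c)^2 + (w/2)^2) over (lo, hi)
  seg <- function(c0, w, A, lo, hi) {
    A * (w / 2) * (atan((hi - c0) / (w / 2)) - atan((lo - c0) / (w / 2)))
  }
  win <- exclusions$window
  tot <- 0; excl <- 0
  for (i in seq_len(nrow(s$excipient_peaks))) {
    p <- s$excipient_peaks[i, ]
    tot <- tot + seg(p$center, p$width, p$amplitude, win[1], win[2])
    for (k in seq_len(nrow(exclusions$intervals))) {
      iv <- exclusions$intervals[k, ]
      excl <- excl + seg(p$center, p$width, p$amplitude, iv[1], iv[2])
    }
  }
  excl / tot
}

#' Scenario for synthetic 2D methyl peak lists
#'
#' Emulates a picked methyl-region peak list (default 48 peaks spanning
#' 0.2-1.4 ppm 1H and 12-27 ppm 13C) with ppb-scale chemical shift jitter and
#' percent-scale height jitter between lots. The most intense base peak is
#' the designated reference for relative intensities. Peak s/n is assigned as
#' `height / noise_floor`.
#'
#' @param n_peaks number of peaks (default 48).
#' @param proton_range,hetero_range shift ranges in ppm.
#' @param height_range base peak height range (arbitrary units).
#' @param jitter_h_ppb,jitter_x_ppb per-lot shift jitter standard deviations
#'   in ppb (defaults 1 and 5).
#' @param height_rel_sd per-lot relative height jitter (default 0.04, the
#'   percent-scale lot-to-lot variation seen in drug product repeats).
#' @param noise_floor s/n denominator.
#' @param base_shifts optional n x 2 matrix (1H, 13C) overriding the drawn
#'   base positions; `base_heights` likewise.
#' @param brand_effect optional list `brand`, `label`, `d_h_ppb`, `d_x_ppb`,
#'   `height_factor` injected into that brand's lots.
#' @param seed master seed.
#' @return A `peaklist_scenario` list; base positions/heights are drawn once
#'   from the seed and shared by all lots.
#' @export
peaklist_scenario <- function(n_peaks = 48, proton_range = c(0.2, 1.4),
                              hetero_range = c(12, 27), height_range = c(2e6, 8e6),
                              jitter_h_ppb = 1, jitter_x_ppb = 5,
                              height_rel_sd = 0.04, noise_floor = 4e4,
                              base_shifts = NULL, base_heights = NULL,
                              brand_effect = NULL, seed = 1L) {
  stopifnot(n_peaks >= 1, jitter_h_ppb >= 0, jitter_x_ppb >= 0, height_rel_sd >= 0)
  base <- with_substream(seed, "peakbase", {
    sh <- if (is.null(base_shifts)) {
      cbind(stats::runif(n_peaks, proton_range[1], proton_range[2]),
            stats::runif(n_peaks, hetero_range[1], hetero_range[2]))
    } else as.matrix(base_shifts)
    hh <- if (is.null(base_heights)) {
      stats::runif(n_peaks, height_range[1], height_range[2])
    } else as.numeric(base_heights)
    list(shifts = sh, heights = hh)
  })
  labels <- sprintf("pk%02d", seq_len(n_peaks))
  structure(
    list(n_peaks = n_peaks, labels = labels,
         base_shifts = base$shifts, base_heights = base$heights,
         reference_label = labels[which.max(base$heights)],
         jitter_h_ppb = jitter_h_ppb, jitter_x_ppb = jitter_x_ppb,
         height_rel_sd = height_rel_sd, noise_floor = noise_floor,
         brand_effect = brand_effect, seed = as.integer(seed)),
    class = "peaklist_scenario")
}

#' Simulate per-lot 2D peak lists for a two-brand study
#'
#' Brand A lots are unperturbed; brand B lots carry the scenario's brand
#' effect. The returned truth table records the per-peak injected shift
#' differences (ppb) and height factors so downstream estimates can be
#' checked against ground truth.
#'
#' @param s a [peaklist_scenario].
#' @param m,n lot counts per brand (each >= 2).
#' @param brand_a,brand_b brand labels.
#' @return List: `lists` (peak lists with brand/lot attributes, brand A
#'   first), `manifest`, `truth` (data.frame `peak_label`, `true_d_h_ppb`,
#'   `true_d_x_ppb`, `true_height_factor`), `reference_label`.
#' @export
simulate_peaklists <- function(s, m = 5, n = 5, brand_a = "A", brand_b = "B") {
  stopifnot(inherits(s, "peaklist_scenario"), m >= 2, n >= 2)
  manifest <- data.frame(
    brand = c(rep(brand_a, m), rep(brand_b, n)),
    lot = c(sprintf("%s%02d", brand_a, seq_len(m)), sprintf("%s%02d", brand_b, seq_len(n))),
    stringsAsFactors = FALSE)
  be <- s$brand_effect
  truth <- data.frame(peak_label = s$labels,
                      true_d_h_ppb = 0, true_d_x_ppb = 0, true_height_factor = 1,
                      stringsAsFactors = FALSE)
  if (!is.null(be)) {
    i <- match(be$label, s$labels)
    if (is.na(i)) stop("simulate_peaklists: brand effect names unknown label", call. = FALSE)
    truth$true_d_h_ppb[i] <- be$d_h_ppb %||% 0
    truth$true_d_x_ppb[i] <- be$d_x_ppb %||% 0
    truth$true_height_factor[i] <- be$height_factor %||% 1
  }
  lists <- lapply(seq_len(nrow(manifest)), function(r) {
    brand <- manifest$brand[r]; lot <- manifest$lot[r]
    with_substream(s$seed, paste("peaks", brand, lot, sep = "/"), {
      h <- s$base_shifts[, 1] + stats::rnorm(s$n_peaks, 0, s$jitter_h_ppb / 1000)
      x <- s$base_shifts[, 2] + stats::rnorm(s$n_peaks, 0, s$jitter_x_ppb / 1000)
      ht <- s$base_heights * pmax(1 + stats::rnorm(s$n_peaks, 0, s$height_rel_sd), 1e-6)
      if (identical(brand, brand_b)) {
        h <- h + truth$true_d_h_ppb / 1000
        x <- x + truth$true_d_x_ppb / 1000
        ht <- ht * truth$true_height_factor
      }
      pk <- data.frame(label = s$labels, proton_shift = h, hetero_shift = x,
                       height = ht, snr = ht / s$noise_floor,
                       stringsAsFactors = FALSE)
      as_peaklist(pk, brand, lot)
    })
  })
  list(lists = lists, manifest = manifest, truth = truth,
       reference_label = s$reference_label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
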