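#' Run a configured similarity analysis
#'
#' Executes the analyses named in a JSON run configuration and assembles a
#' combined comparison report. Config layout (all sections optional, at least
#' one required):
#' \preformatted{
#' {
#'   "seed": 1,
#'   "dm": {"manifest": "spectra.json", "bin_width": 0.01, "components": 3,
#'          "threshold": 3.3, "window": [0, 8],
#'          "brand_a": "X", "brand_b": "Y"},
#'   "peak_profile": {"manifest": "peaks.json", "reference": "Thr-d",
#'                    "alpha": 0.05, "dh": 4, "dx": 15, "snr_threshold": 10},
#'   "expected_peaks": {"fasta": "seq.fa", "detected": 29}
#' }
#' }
#' Relative paths resolve against the config file's directory. Re-running the
#' same config reproduces all numeric content (any stochastic step is fixed
#' by the config seed).
#'
#' @param config path to the JSON run configuration.
#' @param out_dir optional directory for the written report
#'   (see [write_report()]); `NULL` writes nothing.
#' @return An object of class `comparison_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!file.exists(config)) stop("run_pipeline: config not found: ", config, call. = FALSE)
  cfg <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  base <- dirname(normalizePath(config))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  sections <- intersect(c("dm", "peak_profile", "expected_peaks"), names(cfg))
  if (!length(sections)) {
    stop("run_pipeline: config must request at least one analysis ",
         "(dm, peak_profile or expected_peaks)", call. = FALSE)
  }
  rep <- list(provenance = list(
    config = normalizePath(config),
    config_sha1 = unname(tools::md5sum(config)),
    seed = cfg$seed %||% NA_integer_,
    version = as.character(utils::packageVersion("hosnmr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  if ("dm" %in% sections) {
    d <- cfg$dm
    manifest <- read_group_manifest(resolve(d$manifest))
    spectra <- load_manifest_spectra(manifest)
    win <- if (is.null(d$window)) c(0, 8) else as.numeric(d$window)
    excl <- if (is.null(d$exclusions)) default_exclusions(win) else {
      exclusion_set(matrix(as.numeric(unlist(d$exclusions)), ncol = 2, byrow = TRUE), win)
    }
    rep$dm <- dm_pipeline(spectra,
                          brand_a = d$brand_a %||% NULL, brand_b = d$brand_b %||% NULL,
                          exclusions = excl,
                          bin_width = d$bin_width %||% 0.01,
                          n_components = d$components %||% 3,
                          threshold = d$threshold %||% 3.3)
  }
  if ("peak_profile" %in% sections) {
    p <- cfg$peak_profile
    manifest <- read_group_manifest(resolve(p$manifest))
    lists <- load_manifest_peaklists(manifest, snr_threshold = p$snr_threshold %||% NULL)
    ps <- match_peaks(lists,
                      tol_h = p$tol_h %||% 0.010, tol_x = p$tol_x %||% 0.050)
    brands <- unique(vapply(lists, function(l) attr(l, "brand"), ""))
    brand_a <- p$brand_a %||% brands[1]
    brand_b <- p$brand_b %||% setdiff(brands, brand_a)[1]
    refl <- p$reference %||% stop("run_pipeline: peak_profile needs a reference peak label")
    alpha <- p$alpha %||% 0.05
    relint <- relative_intensities(ps, refl)
    cmp <- compare_intensities(relint, brand_a, brand_b, refl, alpha = alpha)
    rep$peak_profile <- list(
      peak_set = ps,
      shift_differences = shift_differences(ps, brand_a, brand_b,
                                            h_threshold = p$dh %||% 4,
                                            x_threshold = p$dx %||% 15),
      intensity_comparisons = cmp,
      equivalence = equivalence_summary(cmp, alpha = alpha),
      brand_a = brand_a, brand_b = brand_b, reference_label = refl, alpha = alpha)
  }
  if ("expected_peaks" %in% sections) {
    e <- cfg$expected_peaks
    seq <- read_fasta_sequence(resolve(e$fasta))
    exp <- expected_peak_count(seq, include_arg_he = isTRUE(e$include_arg_he))
    rep$expected_peaks <- list(
      name = seq$name, expected = exp,
      coverage = if (!is.null(e$detected)) coverage_fraction(e$detected, exp) else NULL)
  }
  class(rep) <- "comparison_report"
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

format_report <- function(rep) {
  out <- c("== HOS similarity report ==",
           sprintf("version %s  seed %s", rep$provenance$version, rep$provenance$seed))
  if (!is.null(rep$dm)) {
    r <- rep$dm$dm_result
    ev <- rep$dm$pca$explained_fraction
    out <- c(out, "",
             sprintf("[1D chemometrics] D_M = %.3f (threshold %.2f) -> %s",
                     r$dm, r$threshold, r$verdict),
             sprintf("  PC1-2 explained variance: %.1f%%", 100 * sum(ev[1:2])))
  }
  if (!is.null(rep$peak_profile)) {
    pp <- rep$peak_profile
    eq <- pp$equivalence
    sd_ <- pp$shift_differences
    out <- c(out, "",
             sprintf("[2D peak profile] %s vs %s, reference %s, alpha %.2g",
                     pp$brand_a, pp$brand_b, pp$reference_label, pp$alpha),
             sprintf("  max |ddelta| 1H = %.1f ppb, hetero = %.1f ppb; %d/%d within metric",
                     max(abs(sd_$delta_h)), max(abs(sd_$delta_x)),
                     sum(sd_$within_metric), nrow(sd_)),
             sprintf("  equivalent relative heights: %d/%d (%.0f%%)",
                     eq$equivalent, eq$total, eq$fraction))
  }
  if (!is.null(rep$expected_peaks)) {
    ep <- rep$expected_peaks
    line <- sprintf("[amide count] %s: %d expected peaks", ep$name, ep$expected)
    if (!is.null(ep$coverage)) {
      line <- sprintf("%s; %d detected -> %d%% coverage (%s)", line,
                      ep$coverage$detected, ep$coverage$percent_rounded, ep$coverage$band)
    }
    out <- c(out, "", line)
  }
  out
}

#' Write a comparison report to disk
#'
#' Produces `report.txt` (human-readable, values at display precision: p to 2
#' significant figures, shift differences to 0.1 ppb) and full-precision
#' delimited tables (`scores.tsv`, `shift_differences.tsv`,
#' `intensity_comparisons.tsv`) for the sections present.
#'
#' @param rep a `comparison_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(format_report(rep), file.path(out_dir, "report.txt"))
  wt <- function(df, f) utils::write.table(df, file.path(out_dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  if (!is.null(rep$dm)) {
    sc <- data.frame(rep$dm$bin_matrix$lots, rep$dm$pca$scores)
    names(sc) <- c("brand", "lot", paste0("PC", seq_len(ncol(rep$dm$pca$scores))))
    wt(sc, "scores.tsv")
  }
  if (!is.null(rep$peak_profile)) {
    wt(rep$peak_profile$shift_differences, "shift_differences.tsv")
    wt(rep$peak_profile$intensity_comparisons, "intensity_comparisons.tsv")
  }
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `dm`, `peak-profile`,
#' `expected-peaks` and `report` (see the `inst/cli/hos` wrapper script).
#' Arguments are `--key value` pairs; see the package vignette for the
#' options of each subcommand.
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
hos_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hos <subcommand> [--key value ...]",
    "  simulate       --out <dir> [--seed n] [--m n] [--n n] [--effect-shift ppm] [--effect-peak i]",
    "  dm             --manifest <json> [--bin-width w] [--components p] [--threshold t]",
    "  peak-profile   --manifest <json> --reference <label> [--alpha a] [--dh ppb] [--dx ppb]",
    "  expected-peaks --fasta <file> [--detected n]",
    "  report         --config <json> [--out <dir>]", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  sub <- args[1]; rest <- args[-1]
  opts <- list()
  i <- 1L
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--")) stop("hos: unexpected argument: ", rest[i], call. = FALSE)
    key <- gsub("-", "_", substring(rest[i], 3))
    opts[[key]] <- if (i < length(rest) && !startsWith(rest[i + 1], "--")) {
      i <- i + 1L; rest[i]
    } else TRUE
    i <- i + 1L
  }
  numo <- function(k, d) if (is.null(opts[[k]])) d else as.numeric(opts[[k]])

  status <- 0L
  if (sub == "simulate") {
    out <- opts$out %||% stop("hos simulate: --out required", call. = FALSE)
    seed <- as.integer(numo("seed", 1))
    m <- as.integer(numo("m", 7)); n <- as.integer(numo("n", 3))
    eff <- if (!is.null(opts$effect_shift)) {
      list(brand = "B", peak_index = as.integer(numo("effect_peak", 13)),
           shift = as.numeric(opts$effect_shift), amp_factor = 1)
    } else NULL
    st <- simulate_group_study(spectrum_scenario(seed = seed, brand_effect = eff), m, n)
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    members <- lapply(seq_along(st$spectra), function(k) {
      sp <- st$spectra[[k]]
      f <- sprintf("%s_%s.txt", sp$brand, sp$lot)
      write_spectrum1d(sp, file.path(out, f))
      list(lot = sp$lot, path = f, kind = "spectrum1d", dialect = "xy_text")
    })
    brands <- lapply(unique(st$manifest$brand), function(b) {
      list(brand = b, members = members[st$manifest$brand == b])
    })
    jsonlite::write_json(list(brands = brands), file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    message("hos simulate: wrote ", length(members), " spectra + manifest.json to ", out)
  } else if (sub == "dm") {
    manifest <- read_group_manifest(opts$manifest %||% stop("--manifest required", call. = FALSE))
    res <- dm_pipeline(load_manifest_spectra(manifest),
                       bin_width = numo("bin_width", 0.01),
                       n_components = as.integer(numo("components", 3)),
                       threshold = numo("threshold", 3.3))
    print(res$dm_result)
  } else if (sub == "peak-profile") {
    manifest <- read_group_manifest(opts$manifest %||% stop("--manifest required", call. = FALSE))
    lists <- load_manifest_peaklists(manifest)
    ps <- match_peaks(lists)
    brands <- unique(manifest$brand[manifest$kind == "peaklist2d"])
    refl <- opts$reference %||% stop("--reference required", call. = FALSE)
    relint <- relative_intensities(ps, refl)
    cmp <- compare_intensities(relint, brands[1], brands[2], refl, alpha = numo("alpha", 0.05))
    eq <- equivalence_summary(cmp, alpha = numo("alpha", 0.05))
    sd_ <- shift_differences(ps, brands[1], brands[2],
                             h_threshold = numo("dh", 4), x_threshold = numo("dx", 15))
    cat(sprintf("peaks: %d; within ddelta metric: %d; equivalent heights: %d/%d (%.0f%%)\n",
                nrow(sd_), sum(sd_$within_metric), eq$equivalent, eq$total, eq$fraction))
  } else if (sub == "expected-peaks") {
    seq <- read_fasta_sequence(opts$fasta %||% stop("--fasta required", call. = FALSE))
    exp <- expected_peak_count(seq)
    cat(sprintf("%s: %d expected peaks\n", seq$name, exp))
    if (!is.null(opts$detected)) {
      cv <- coverage_fraction(as.integer(opts$detected), exp)
      cat(sprintf("coverage: %d%% (%s)\n", cv$percent_rounded, cv$band))
    }
  } else if (sub == "report") {
    rep <- run_pipeline(opts$config %||% stop("--config required", call. = FALSE),
                        out_dir = opts$out %||% NULL)
    print(rep)
  } else {
    message(usage)
    status <- 2L
  }
  invisible(status)
}
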