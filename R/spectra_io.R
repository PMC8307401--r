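#' One-dimensional frequency-domain NMR spectrum
#'
#' Container for a processed 1D spectrum: a chemical-shift axis (ppm) with one
#' real intensity per point, plus brand/lot identification and optional
#' acquisition metadata. The axis is stored in descending ppm (NMR display
#' convention); ascending input is accepted and flipped on construction.
#'
#' @param ppm numeric chemical-shift axis, strictly monotonic (either
#'   direction), length >= 2.
#' @param intensity numeric intensities, same length as `ppm`, all finite.
#' @param brand,lot character labels identifying the drug product brand and
#'   manufacturing lot.
#' @param field_mhz optional spectrometer 1H frequency (MHz), metadata only.
#' @param nucleus observed nucleus label, default `"1H"`.
#' @return An object of class `spectrum1d`: a list with elements `ppm`,
#'   `intensity`, `brand`, `lot`, `field_mhz`, `nucleus`.
#' @examples
#' sp <- spectrum1d(c(9, 8, 7), c(0, 1, 0), brand = "A", lot = "1")
#' sp$ppm
#' @export
spectrum1d <- function(ppm, intensity, brand = NA_character_, lot = NA_character_,
                       field_mhz = NA_real_, nucleus = "1H") {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) < 2L || length(ppm) != length(intensity)) {
    stop("spectrum1d: ppm and intensity must have equal length >= 2", call. = FALSE)
  }
  d <- diff(ppm)
  if (all(d > 0)) {
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  } else if (!all(d < 0)) {
    stop("spectrum1d: ppm axis must be strictly monotonic", call. = FALSE)
  }
  if (anyNA(ppm) || any(!is.finite(ppm))) {
    stop("spectrum1d: non-finite values in ppm axis", call. = FALSE)
  }
  if (anyNA(intensity) || any(!is.finite(intensity))) {
    stop("spectrum1d: non-finite intensity values", call. = FALSE)
  }
  structure(
    list(ppm = ppm, intensity = intensity,
         brand = as.character(brand), lot = as.character(lot),
         field_mhz = field_mhz, nucleus = nucleus),
    class = "spectrum1d"
  )
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s / %s: %d points, %.3f..%.3f ppm (%s)\n",
              x$brand, x$lot, length(x$ppm),
              max(x$ppm), min(x$ppm), x$nucleus))
  invisible(x)
}

#' Read a 1D spectrum from disk
#'
#' Supports two dialects: `"xy_text"`, a two-column delimited text file
#' (ppm, intensity; whitespace or comma separated, `#` comments allowed), and
#' `"jcamp"`, a single-block JCAMP-DX file with an `XYDATA` or `XYPOINTS`
#' record in AFFN (plain-number) form. The axis is normalized to descending
#' ppm regardless of the order on disk.
#'
#' @param path file path.
#' @param dialect `"xy_text"` or `"jcamp"`; default guesses from the file
#'   extension (`.dx`/`.jdx` are JCAMP).
#' @param brand,lot,field_mhz,nucleus metadata attached to the result; for
#'   JCAMP input, header fields are used when arguments are missing.
#' @return A [spectrum1d] object.
#' @export
read_spectrum1d <- function(path, dialect = c("auto", "xy_text", "jcamp"),
                            brand = NA_character_, lot = NA_character_,
                            field_mhz = NA_real_, nucleus = "1H") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_spectrum1d: file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) %in% c("dx", "jdx")) "jcamp" else "xy_text"
  }
  if (dialect == "jcamp") {
    jc <- read_jcampdx(path)
    if (is.na(field_mhz) && !is.null(jc$field_mhz)) field_mhz <- jc$field_mhz
    if (nucleus == "1H" && !is.null(jc$nucleus)) nucleus <- jc$nucleus
    return(spectrum1d(jc$x, jc$y, brand = brand, lot = lot,
                      field_mhz = field_mhz, nucleus = nucleus))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("read_spectrum1d: no data rows in ", path, call. = FALSE)
  fields <- strsplit(gsub(",", " ", lines), "[[:space:]]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop(sprintf("read_spectrum1d: line %d of %s has fewer than 2 columns", bad[1], path),
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  badx <- which(is.na(x) | is.na(y))
  if (length(badx)) {
    stop(sprintf("read_spectrum1d: non-numeric or NaN value at line %d of %s", badx[1], path),
         call. = FALSE)
  }
  spectrum1d(x, y, brand = brand, lot = lot, field_mhz = field_mhz, nucleus = nucleus)
}

#' Write a 1D spectrum as two-column text
#'
#' Full double precision is retained so a read/write round trip is exact.
#'
#' @param spectrum a [spectrum1d].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum1d <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  writeLines(
    c(sprintf("# spectrum1d brand=%s lot=%s nucleus=%s", spectrum$brand,
              spectrum$lot, spectrum$nucleus),
      paste(format(spectrum$ppm, digits = 17, trim = TRUE, scientific = FALSE),
            format(spectrum$intensity, digits = 17, trim = TRUE))),
    path)
  invisible(path)
}

#' Read a 2D peak list
#'
#' Reads picked 2D cross-peak tables in either a whitespace-delimited
#' Sparky-like layout or a delimited file with a header row. The canonical
#' header columns are `label`, `w1_ppm` (1H), `w2_ppm` (13C or 15N), `height`
#' and optionally `snr`; a headerless Sparky-like file is taken as
#' `label w1 w2 height [snr]` in that order.
#'
#' @param path file path.
#' @param dialect `"delimited"` (header row, default) or `"sparky_like"`.
#' @param brand,lot metadata attached as attributes.
#' @return A `data.frame` of class `peaklist2d` with columns `label`,
#'   `proton_shift`, `hetero_shift`, `height`, `snr` (NA when absent), in file
#'   order.
#' @export
read_peaklist <- function(path, dialect = c("delimited", "sparky_like"),
                          brand = NA_character_, lot = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_peaklist: file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (dialect == "delimited" && length(lines)) {
    hdr <- tolower(strsplit(gsub(",", " ", lines[1]), "[[:space:]]+")[[1]])
    if (!any(grepl("ppm|w1|label", hdr))) {
      dialect <- "sparky_like"  # no recognizable header; fall back
    } else {
      lines <- lines[-1]
    }
  }
  if (!length(lines)) {
    warning("read_peaklist: empty peak list in ", path)
    pk <- data.frame(label = character(), proton_shift = numeric(),
                     hetero_shift = numeric(), height = numeric(), snr = numeric())
    return(as_peaklist(pk, brand, lot))
  }
  fields <- strsplit(gsub(",", " ", lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("read_peaklist: row %d has fewer than 4 columns (label w1 w2 height)",
                 which(nf < 4L)[1]), call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) f[i], "")
  pk <- data.frame(
    label = get(1L),
    proton_shift = as.numeric(get(2L)),
    hetero_shift = as.numeric(get(3L)),
    height = as.numeric(get(4L)),
    snr = ifelse(nf >= 5L, suppressWarnings(as.numeric(get(5L))), NA_real_),
    stringsAsFactors = FALSE
  )
  if (anyNA(pk$proton_shift) || anyNA(pk$hetero_shift) || anyNA(pk$height)) {
    stop("read_peaklist: non-numeric shift or height field in ", path, call. = FALSE)
  }
  as_peaklist(pk, brand, lot)
}

as_peaklist <- function(pk, brand = NA_character_, lot = NA_character_) {
  if (nrow(pk)) {
    if (any(pk$height <= 0)) {
      stop("read_peaklist: peak height must be > 0 (offending label: ",
           pk$label[which(pk$height <= 0)[1]], ")", call. = FALSE)
    }
    if (anyDuplicated(pk$label)) {
      stop("read_peaklist: duplicate peak labels: ",
           paste(unique(pk$label[duplicated(pk$label)]), collapse = ", "), call. = FALSE)
    }
    if (any(!is.na(pk$snr) & pk$snr < 0)) {
      stop("read_peaklist: snr must be >= 0", call. = FALSE)
    }
  }
  attr(pk, "brand") <- as.character(brand)
  attr(pk, "lot") <- as.character(lot)
  class(pk) <- c("peaklist2d", "data.frame")
  pk
}

#' Write a 2D peak list in the canonical delimited dialect
#'
#' @param peaks a `peaklist2d` data frame (see [read_peaklist]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  has_snr <- any(!is.na(peaks$snr))
  hdr <- if (has_snr) "label w1_ppm w2_ppm height snr" else "label w1_ppm w2_ppm height"
  rows <- paste(peaks$label,
                format(peaks$proton_shift, digits = 17, trim = TRUE),
                format(peaks$hetero_shift, digits = 17, trim = TRUE),
                format(peaks$height, digits = 17, trim = TRUE),
                if (has_snr) format(peaks$snr, digits = 17, trim = TRUE) else NULL)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Filter peaks by signal-to-noise ratio
#'
#' Retains peaks whose s/n is strictly greater than the threshold (the field
#' convention "s/n higher than 10"), preserving input order.
#'
#' @param peaks a `peaklist2d` data frame.
#' @param threshold non-negative s/n cutoff; default 10.
#' @return The filtered `peaklist2d`.
#' @export
filter_by_snr <- function(peaks, threshold = 10) {
  stopifnot(threshold >= 0)
  if (threshold > 0 && anyNA(peaks$snr)) {
    stop("filter_by_snr: peaks without recorded snr cannot be filtered at threshold > 0",
         call. = FALSE)
  }
  out <- peaks[is.na(peaks$snr) | peaks$snr > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a group manifest
#'
#' A manifest maps each brand to its lots and data files. JSON layout:
#' \preformatted{
#' {"brands": [
#'   {"brand": "Rituxan", "members": [
#'     {"lot": "L1", "path": "l1.txt", "kind": "spectrum1d", "dialect": "xy_text"}
#' ]}]}
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest JSON file.
#' @return A data.frame with columns `brand`, `lot`, `path`, `kind`,
#'   `dialect`, one row per member.
#' @export
read_group_manifest <- function(path) {
  if (!file.exists(path)) stop("read_group_manifest: file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(cfg$brands) || !length(cfg$brands)) {
    stop("read_group_manifest: manifest must list at least one brand", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  rows <- list()
  for (b in cfg$brands) {
    if (is.null(b$members) || !length(b$members)) {
      stop("read_group_manifest: brand ", b$brand, " has no members", call. = FALSE)
    }
    lots <- vapply(b$members, function(m) as.character(m$lot), "")
    if (anyDuplicated(lots)) {
      stop("read_group_manifest: duplicate lot labels within brand ", b$brand, call. = FALSE)
    }
    for (m in b$members) {
      p <- as.character(m$path)
      if (!file.exists(p)) p <- file.path(base, p)
      rows[[length(rows) + 1L]] <- data.frame(
        brand = as.character(b$brand), lot = as.character(m$lot), path = p,
        kind = if (is.null(m$kind)) "spectrum1d" else as.character(m$kind),
        dialect = if (is.null(m$dialect)) "auto" else as.character(m$dialect),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  bad <- setdiff(out$kind, c("spectrum1d", "peaklist2d"))
  if (length(bad)) stop("read_group_manifest: unknown member kind: ", bad[1], call. = FALSE)
  out
}

#' Load all 1D spectra named by a manifest
#'
#' @param manifest data.frame from [read_group_manifest] (or of the same shape).
#' @return List of [spectrum1d] objects in manifest order.
#' @export
load_manifest_spectra <- function(manifest) {
  rows <- manifest[manifest$kind == "spectrum1d", , drop = FALSE]
  if (!nrow(rows)) stop("load_manifest_spectra: manifest names no 1D spectra", call. = FALSE)
  lapply(seq_len(nrow(rows)), function(i) {
    d <- rows$dialect[i]
    read_spectrum1d(rows$path[i], dialect = if (is.na(d)) "auto" else d,
                    brand = rows$brand[i], lot = rows$lot[i])
  })
}

#' Load all 2D peak lists named by a manifest
#'
#' @param manifest data.frame from [read_group_manifest].
#' @param snr_threshold optional s/n filter applied to each list (strict `>`);
#'   `NULL` to skip.
#' @return List of `peaklist2d` data frames in manifest order.
#' @export
load_manifest_peaklists <- function(manifest, snr_threshold = NULL) {
  rows <- manifest[manifest$kind == "peaklist2d", , drop = FALSE]
  if (!nrow(rows)) stop("load_manifest_peaklists: manifest names no peak lists", call. = FALSE)
  lapply(seq_len(nrow(rows)), function(i) {
    d <- rows$dialect[i]
    pk <- read_peaklist(rows$path[i],
                        dialect = if (is.na(d) || d == "auto") "delimited" else d,
                        brand = rows$brand[i], lot = rows$lot[i])
    if (!is.null(snr_threshold)) pk <- filter_by_snr(pk, snr_threshold)
    pk
  })
}
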