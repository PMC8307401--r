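# Minimal single-block JCAMP-DX support for frequency-domain 1D traces.
# Handles AFFN (plain-number) XYPOINTS blocks and equidistant X++(Y..Y) XYDATA
# blocks with XFACTOR/YFACTOR/FIRSTX/LASTX/NPOINTS; compressed SQZ/DIF/DUP
# encodings are out of scope.

read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    i <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    sub("^##[^=]*=\\s*", "", lines[i[1]])
  }
  num <- function(name) {
    v <- ldr(name)
    if (is.null(v)) NULL else suppressWarnings(as.numeric(v))
  }
  meta <- list(field_mhz = num("\\.OBSERVE FREQUENCY"),
               nucleus = {
                 n <- ldr("\\.OBSERVE NUCLEUS")
                 if (is.null(n)) NULL else gsub("[\\^ ]", "", n)
               })

  i_xy <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  i_xd <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  block_end <- function(start) {
    rest <- grep("^##", lines[-seq_len(start)])
    if (length(rest)) start + rest[1] - 1L else length(lines)
  }

  if (length(i_xy)) {
    body <- lines[(i_xy[1] + 1L):block_end(i_xy[1])]
    body <- body[!grepl("^##", body)]
    toks <- strsplit(trimws(gsub("[,;]", " ", body)), "[[:space:]]+")
    vals <- suppressWarnings(as.numeric(unlist(toks)))
    vals <- vals[!is.na(vals)]
    if (length(vals) %% 2L != 0L) {
      stop("read_jcampdx: odd number of values in XYPOINTS block of ", path, call. = FALSE)
    }
    m <- matrix(vals, ncol = 2L, byrow = TRUE)
    return(c(list(x = m[, 1], y = m[, 2]), meta))
  }

  if (length(i_xd)) {
    xf <- num("XFACTOR"); if (is.null(xf) || is.na(xf)) xf <- 1
    yf <- num("YFACTOR"); if (is.null(yf) || is.na(yf)) yf <- 1
    firstx <- num("FIRSTX"); lastx <- num("LASTX"); np <- num("NPOINTS")
    if (is.null(firstx) || is.null(lastx) || is.null(np)) {
      stop("read_jcampdx: XYDATA block missing FIRSTX/LASTX/NPOINTS in ", path, call. = FALSE)
    }
    body <- lines[(i_xd[1] + 1L):block_end(i_xd[1])]
    body <- body[!grepl("^##", body)]
    y <- numeric(0)
    for (ln in body) {
      toks <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      v <- suppressWarnings(as.numeric(toks))
      if (anyNA(v)) {
        stop("read_jcampdx: non-AFFN token '", toks[which(is.na(v))[1]],
             "' in XYDATA of ", path, " (compressed encodings unsupported)", call. = FALSE)
      }
      if (length(v) >= 2L) y <- c(y, v[-1L])  # first value per line is the X check value
    }
    if (length(y) != np) {
      stop(sprintf("read_jcampdx: NPOINTS=%d but %d ordinates found in %s",
                   np, length(y), path), call. = FALSE)
    }
    x <- seq(firstx, lastx, length.out = np) * xf
    return(c(list(x = x, y = y * yf), meta))
  }
  stop("read_jcampdx: no XYPOINTS or XYDATA block in ", path, call. = FALSE)
}

#' Write a 1D spectrum as a single-block JCAMP-DX file
#'
#' Emits an AFFN `XYPOINTS` block (exact x,y pairs, full precision), the most
#' portable uncompressed JCAMP-DX form.
#'
#' @param spectrum a [spectrum1d].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jcampdx <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  hdr <- c(
    sprintf("##TITLE=%s %s", spectrum$brand, spectrum$lot),
    "##JCAMP-DX=5.01",
    "##DATA TYPE=NMR SPECTRUM",
    sprintf("##.OBSERVE NUCLEUS=%s", spectrum$nucleus),
    if (!is.na(spectrum$field_mhz)) sprintf("##.OBSERVE FREQUENCY=%.6f", spectrum$field_mhz),
    "##XUNITS=PPM", "##YUNITS=ARBITRARY UNITS",
    sprintf("##NPOINTS=%d", length(spectrum$ppm)),
    "##XYPOINTS=(XY..XY)")
  body <- paste(format(spectrum$ppm, digits = 17, trim = TRUE, scientific = FALSE),
                format(spectrum$intensity, digits = 17, trim = TRUE), sep = ", ")
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}
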