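# Spectral power distributions: container, file ingest, normalization.

#' Spectral curves
#'
#' A `spectral_curve` holds a sampled spectral power distribution: ascending
#' wavelengths in nanometers within \[380, 780\] and nonnegative relative
#' power. All downstream indices (CCT, CRI, TLCI) are invariant to the
#' curve's absolute scale.
#'
#' @param wavelength ascending numeric vector of wavelengths (nm).
#' @param value nonnegative relative power, same length.
#' @param label optional source label carried through reports.
#' @return object of class `spectral_curve`.
#' @export
spectral_curve <- function(wavelength, value, label = "") {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have equal length")
  if (length(wavelength) < 2) stop("a spectral curve needs at least 2 samples")
  o <- order(wavelength)
  wavelength <- wavelength[o]; value <- value[o]
  if (any(duplicated(wavelength))) stop("duplicated wavelengths")
  if (any(!is.finite(wavelength)) || any(!is.finite(value)))
    stop("non-finite values in spectral curve")
  if (any(value < 0)) stop("negative spectral power")
  keep <- wavelength >= 380 & wavelength <= 780
  if (sum(keep) < 2) stop("spectral curve has fewer than 2 samples in 380-780 nm")
  structure(list(wavelength = wavelength[keep], value = value[keep],
                 label = label),
            class = "spectral_curve")
}

#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve%s: %d samples, %g-%g nm, peak %.4g at %g nm>\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              max(x$value), x$wavelength[which.max(x$value)]))
  invisible(x)
}

#' Resample a spectral curve to the canonical 5 nm grid
#'
#' Linear interpolation onto 380, 385, ..., 780 nm. Grid points outside the
#' measured support are set to zero (no measured power). Resampling a curve
#' already on the grid returns it unchanged (idempotent).
#'
#' @param spd a `spectral_curve`.
#' @return a `spectral_curve` on the canonical grid.
#' @export
spd_resample <- function(spd) {
  stopifnot(inherits(spd, "spectral_curve"))
  if (identical(spd$wavelength, .spd_grid)) return(spd)
  v <- stats::approx(spd$wavelength, spd$value, .spd_grid,
                     method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  spectral_curve(.spd_grid, v, spd$label)
}

# Values of a curve on the canonical grid, as a bare vector.
.spd_values <- function(spd) spd_resample(spd)$value

#' Read a spectrometer SPD export
#'
#' Parses a two-column text file (wavelength nm, relative power). Lines
#' starting with `#` are comments; a single header line of column names is
#' tolerated. Rows are sorted, clipped to 380-780 nm, and resampled to the
#' canonical 5 nm grid.
#'
#' @param path file path.
#' @param dialect `"auto"` (default) sniffs the separator; `"comma"`,
#'   `"semicolon"`, or `"tab"` force one. With the semicolon dialect a
#'   decimal comma is accepted.
#' @param label source label; defaults to the file name.
#' @return a `spectral_curve` on the canonical grid.
#' @export
load_spd <- function(path, dialect = c("auto", "comma", "semicolon", "tab"),
                     label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("SPD file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("SPD file is empty: ", path)
  sep <- switch(dialect,
    comma = ",", semicolon = ";", tab = "\t",
    auto = {
      probe <- lines[[1]]
      if (grepl(";", probe)) ";" else if (grepl(",", probe)) "," else "\t|\\s+"
    })
  parse_row <- function(line) {
    parts <- strsplit(line, sep)[[1]]
    parts <- parts[nzchar(trimws(parts))]
    if (sep == ";") parts <- gsub(",", ".", parts)
    suppressWarnings(as.numeric(trimws(parts)))
  }
  rows <- lapply(lines, parse_row)
  # tolerate one non-numeric header line
  if (length(rows) > 0 && any(is.na(rows[[1]]))) rows <- rows[-1]
  bad <- vapply(rows, function(r) length(r) < 2 || any(is.na(r[1:2])), TRUE)
  if (any(bad))
    stop("SPD parse error at data line ", which(bad)[1], " of ", path)
  m <- do.call(rbind, lapply(rows, function(r) r[1:2]))
  if (nrow(m) < 2) stop("SPD file has fewer than 2 rows: ", path)
  if (any(m[, 2] < 0)) stop("negative spectral power in ", path)
  spd_resample(spectral_curve(m[, 1], m[, 2], label = label))
}

#' Normalize a spectral curve at an anchor wavelength
#'
#' Rescales the curve so its (interpolated) value at the anchor wavelength is
#' exactly 1.0. Spectra are conventionally reported normalized to 1.0 at
#' 555 nm, the peak of photopic sensitivity; since every downstream index is
#' scale invariant this is presentation only.
#'
#' @param spd a `spectral_curve`.
#' @param anchor wavelength in nm, default 555; must lie inside the curve's
#'   support with positive power.
#' @return rescaled `spectral_curve`.
#' @export
normalize_at <- function(spd, anchor = 555) {
  stopifnot(inherits(spd, "spectral_curve"))
  if (anchor < min(spd$wavelength) || anchor > max(spd$wavelength))
    stop("anchor wavelength outside curve support")
  at <- stats::approx(spd$wavelength, spd$value, anchor)$y
  if (!is.finite(at) || at <= 0) stop("zero power at anchor wavelength")
  spectral_curve(spd$wavelength, spd$value / at, spd$label)
}

# --- analytic illuminant families on the canonical grid (bare vectors) ---

# Planck's law, relative spectral radiant exitance; c2 = 1.4388e-2 m K.
.planck_values <- function(T) {
  lam <- .spd_grid * 1e-9
  v <- lam^-5 / expm1(1.4388e-2 / (lam * T))
  v / max(v)
}

# CIE daylight illuminant via the S0/S1/S2 component method.
.daylight_values <- function(T) {
  if (T < 4000 || T > 25000) stop("daylight illuminant defined for 4000-25000 K")
  xd <- if (T <= 7000) {
    0.244063 + 0.09911e3 / T + 2.9678e6 / T^2 - 4.6070e9 / T^3
  } else {
    0.237040 + 0.24748e3 / T + 1.9018e6 / T^2 - 2.0064e9 / T^3
  }
  yd <- -3.000 * xd^2 + 2.870 * xd - 0.275
  M0 <- 0.0241 + 0.2562 * xd - 0.7341 * yd
  M1 <- (-1.3515 - 1.7703 * xd + 5.9114 * yd) / M0
  M2 <- (0.0300 - 31.4424 * xd + 30.0717 * yd) / M0
  s <- .daylight_components()
  v <- s$S0 + M1 * s$S1 + M2 * s$S2
  pmax(v, 0) / max(v)
}
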