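# Packaged CIE data and spectral reflectance reconstruction.
#
# All spectral computation in the package runs on a canonical 5 nm grid over
# 380-780 nm (81 samples). Loaded tables are cached in a package environment.

.chromacal_env <- new.env(parent = emptyenv())

.spd_grid <- seq(380, 780, by = 5)

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "chromacal")
  if (path == "") stop("packaged data file not found: ", file)
  path
}

.cached <- function(key, fn) {
  if (!exists(key, envir = .chromacal_env)) {
    assign(key, fn(), envir = .chromacal_env)
  }
  get(key, envir = .chromacal_env)
}

#' CIE 1931 2-degree color-matching functions
#'
#' Returns the packaged standard-observer color-matching functions on the
#' canonical 5 nm grid (380-780 nm).
#'
#' @return data.frame with columns `wavelength`, `xbar`, `ybar`, `zbar`.
#' @export
cie_cmf <- function() {
  .cached("cmf", function() {
    utils::read.csv(.extdata("cie1931_cmf_2deg_5nm.csv"), comment.char = "#")
  })
}

# Daylight component vectors S0/S1/S2, linearly interpolated from the
# packaged 10 nm table onto the canonical 5 nm grid.
.daylight_components <- function() {
  .cached("s0s1s2", function() {
    d <- utils::read.csv(.extdata("cie_daylight_components_10nm.csv"),
                         comment.char = "#")
    data.frame(
      wavelength = .spd_grid,
      S0 = stats::approx(d$wavelength, d$S0, .spd_grid)$y,
      S1 = stats::approx(d$wavelength, d$S1, .spd_grid)$y,
      S2 = stats::approx(d$wavelength, d$S2, .spd_grid)$y)
  })
}

# Tristimulus integration over the canonical grid. `values` is a vector (or
# matrix with one column per spectrum) sampled on .spd_grid. Returns XYZ rows
# scaled so that Y = 100 corresponds to the illuminant when `normalize` is
# the illuminant spectrum, otherwise raw summation.
.tristimulus <- function(values, normalize = NULL) {
  cmf <- cie_cmf()
  v <- if (is.null(dim(values))) matrix(values, ncol = 1) else values
  xyz <- t(crossprod(as.matrix(cmf[, c("xbar", "ybar", "zbar")]), v))
  if (!is.null(normalize)) {
    k <- 100 / sum(cmf$ybar * normalize)
    xyz <- xyz * k
  }
  colnames(xyz) <- c("X", "Y", "Z")
  xyz
}

# 1960 UCS chromaticity from XYZ rows.
.xyz_to_uv <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  d <- xyz[, 1] + 15 * xyz[, 2] + 3 * xyz[, 3]
  cbind(u = 4 * xyz[, 1] / d, v = 6 * xyz[, 2] / d)
}

#' Reconstruct smooth reflectance spectra from CIELAB anchors
#'
#' For each target color, finds the spectral reflectance on the canonical
#' 5 nm grid that reproduces the target tristimulus values under the given
#' illuminant while minimizing the squared second difference (i.e. the
#' maximally smooth metamer). Bounds \eqn{0 \le R \le 1} are enforced by an
#' active-set iteration. Used to build synthetic spectral stand-ins for
#' physical chart patches and test-color samples whose official reflectance
#' tabulations are not shipped with the package.
#'
#' @param labm n x 3 matrix of Lab targets (under `illuminant`'s white).
#' @param illuminant illuminant spectrum on the canonical grid (default: the
#'   synthesized daylight illuminant at 6504 K, i.e. D65).
#' @return 81 x n matrix of reflectances in \[0, 1\], one column per target.
#' @export
smooth_reflectance <- function(labm, illuminant = NULL) {
  labm <- .as_lab(labm)
  if (is.null(illuminant)) illuminant <- .d65_illuminant()
  cmf <- cie_cmf()
  white <- .tristimulus(illuminant, normalize = illuminant)
  A0 <- t(as.matrix(cmf[, c("xbar", "ybar", "zbar")]) * illuminant) *
    (100 / sum(cmf$ybar * illuminant))
  n <- length(.spd_grid)
  D <- diff(diag(n), differences = 2)
  H <- 2 * crossprod(D) + diag(1e-9, n)
  xyz_t <- lab_to_xyz(labm, white = as.numeric(white))
  out <- matrix(0, n, nrow(labm))
  for (i in seq_len(nrow(labm))) {
    lower <- rep(FALSE, n); upper <- rep(FALSE, n)
    r <- rep(0.5, n)
    for (iter in 1:6) {
      free <- !(lower | upper)
      b <- xyz_t[i, ] - A0 %*% ifelse(upper, 1, 0)
      Af <- A0[, free, drop = FALSE]
      Hf <- H[free, free, drop = FALSE]
      # cross terms from fixed variables in the smoothness penalty
      g <- H[free, !free, drop = FALSE] %*% ifelse(upper[!free], 1, 0)
      K <- rbind(cbind(Hf, t(Af)), cbind(Af, matrix(0, 3, 3)))
      rhs <- c(-g, b)
      sol <- solve(K, rhs)
      r[free] <- sol[seq_len(sum(free))]
      r[lower] <- 0; r[upper] <- 1
      viol_lo <- r < -1e-9; viol_hi <- r > 1 + 1e-9
      if (!any(viol_lo | viol_hi)) break
      lower <- lower | viol_lo
      upper <- upper | viol_hi
      r <- pmin(pmax(r, 0), 1)
    }
    out[, i] <- pmin(pmax(r, 0), 1)
  }
  out
}

# Synthesized D65 (daylight illuminant at 6504 K) on the canonical grid.
.d65_illuminant <- function() {
  .cached("d65_illum", function() .daylight_values(6504))
}

# Reflectance set standing in for the physical ColorChecker patches:
# smoothest metamers of the packaged classic reference values (adapted to
# D65) under synthesized D65.
.chart_reflectances <- function() {
  .cached("chart_refl", function() {
    ref <- reference_chart()
    smooth_reflectance(as.matrix(ref[, c("L_ref", "a_ref", "b_ref")]))
  })
}

# Synthetic stand-ins for the 14 CIE 13.3 test-color samples (see the
# packaged anchor file and the methods vignette).
.tcs_reflectances <- function() {
  .cached("tcs_refl", function() {
    anchors <- utils::read.csv(.extdata("tcs_synthetic_lab.csv"),
                               comment.char = "#")
    smooth_reflectance(as.matrix(anchors[, c("L", "a", "b")]))
  })
}
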