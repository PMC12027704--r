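# Color-space conversions and color-difference metrics.
#
# Conventions: CIELAB coordinates are handled as n x 3 numeric matrices
# (columns L*, a*, b*); a bare length-3 vector is treated as one color.
# sRGB values live in [0, 1] unless an integer bit depth is declared.

.srgb_to_xyz_mat <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3, byrow = TRUE)

.xyz_to_srgb_mat <- solve(.srgb_to_xyz_mat)

# White point of the sRGB encoding (D65), on the Y = 100 scale. Taken as the
# image of RGB = (1,1,1) under the matrix above so that pure white maps to
# exactly L* = 100, a* = b* = 0.
.d65_white <- as.numeric(.srgb_to_xyz_mat %*% c(1, 1, 1)) * 100

.d50_white <- c(96.422, 100, 82.521)

.bradford_mat <- matrix(c(
   0.8951,  0.2664, -0.1614,
  -0.7502,  1.7135,  0.0367,
   0.0389, -0.0685,  1.0296), nrow = 3, byrow = TRUE)

#' Construct CIELAB colors
#'
#' Builds an n x 3 matrix of CIELAB coordinates, validating ranges:
#' `L` must lie in \[0, 100\] and `a`, `b` must be finite. a* and b* for
#' surface colors conventionally span roughly -100..100 but are not clamped.
#'
#' @param L,a,b numeric vectors of equal length (or length 1, recycled).
#' @return numeric matrix with columns `L`, `a`, `b`.
#' @examples
#' lab(50, 3, 4)
#' @export
lab <- function(L, a, b) {
  n <- max(length(L), length(a), length(b))
  m <- cbind(L = rep_len(as.numeric(L), n),
             a = rep_len(as.numeric(a), n),
             b = rep_len(as.numeric(b), n))
  if (any(!is.finite(m))) stop("Lab coordinates must be finite")
  if (any(m[, 1] < -1e-9 | m[, 1] > 100 + 1e-9))
    stop("L* must lie in [0, 100]")
  m
}

.as_lab <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3)
  if (ncol(x) != 3) stop("expected Lab colors as an n x 3 matrix")
  storage.mode(x) <- "double"
  colnames(x) <- c("L", "a", "b")
  x
}

.as_rgb <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3)
  if (ncol(x) != 3) stop("expected RGB colors as an n x 3 matrix")
  storage.mode(x) <- "double"
  x
}

#' CIELAB chroma
#'
#' Distance of a color from the neutral axis, `C* = sqrt(a*^2 + b*^2)`.
#'
#' @param c1 Lab colors (n x 3 matrix or length-3 vector).
#' @return nonnegative numeric vector.
#' @examples
#' chroma(lab(50, 3, 4)) # 5
#' @export
chroma <- function(c1) {
  c1 <- .as_lab(c1)
  as.numeric(sqrt(c1[, 2]^2 + c1[, 3]^2))
}

#' CIELAB color difference (Euclidean)
#'
#' Total color difference `dE* = sqrt(dL*^2 + da*^2 + db*^2)` between two
#' colors in CIELAB; the 1976 formula. Symmetric and a true metric.
#'
#' @param c1,c2 Lab colors (n x 3 matrices or length-3 vectors).
#' @return nonnegative numeric vector.
#' @export
delta_e_cielab <- function(c1, c2) {
  c1 <- .as_lab(c1); c2 <- .as_lab(c2)
  as.numeric(sqrt(rowSums((c1 - c2)^2)))
}

#' CIELAB chroma difference
#'
#' Signed chroma difference `dC* = C1* - C2*`. Deviation summaries report its
#' magnitude; the sign is retained here so the direction (toward or away from
#' neutral) is not lost.
#'
#' @inheritParams delta_e_cielab
#' @return signed numeric vector.
#' @export
delta_c_cielab <- function(c1, c2) {
  chroma(c1) - chroma(c2)
}

#' CIELAB lightness difference
#'
#' Signed lightness difference `dL* = L1* - L2*`.
#'
#' @inheritParams delta_e_cielab
#' @return signed numeric vector.
#' @export
delta_l <- function(c1, c2) {
  c1 <- .as_lab(c1); c2 <- .as_lab(c2)
  as.numeric(c1[, 1] - c2[, 1])
}

# Shared CIEDE2000 intermediates (primed chroma/hue terms, weighting
# functions), following the implementation notes that accompany the published
# verification pair set: hue angles in degrees, the mean-hue branch handles
# |h1' - h2'| > 180 by wrapping into [0, 360).
.ciede2000_terms <- function(c1, c2, kL = 1, kC = 1, kH = 1) {
  if (any(c(kL, kC, kH) <= 0)) stop("CIEDE2000 weights must be positive")
  c1 <- .as_lab(c1); c2 <- .as_lab(c2)
  if (nrow(c1) != nrow(c2)) stop("c1 and c2 must have the same number of colors")
  deg <- pi / 180
  L1 <- c1[, 1]; a1 <- c1[, 2]; b1 <- c1[, 3]
  L2 <- c2[, 1]; a2 <- c2[, 2]; b2 <- c2[, 3]
  Cbar <- (sqrt(a1^2 + b1^2) + sqrt(a2^2 + b2^2)) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, (atan2(b1, a1p) / deg) %% 360)
  h2p <- ifelse(C2p == 0, 0, (atan2(b2, a2p) / deg) %% 360)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dh <- ifelse(dh > 180, dh - 360, ifelse(dh < -180, dh + 360, dh))
  dh <- ifelse(C1p * C2p == 0, 0, dh)
  dHp <- 2 * sqrt(C1p * C2p) * sin(dh / 2 * deg)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))
  Tt <- 1 - 0.17 * cos((hbp - 30) * deg) + 0.24 * cos(2 * hbp * deg) +
    0.32 * cos((3 * hbp + 6) * deg) - 0.20 * cos((4 * hbp - 63) * deg)
  dtheta <- 30 * exp(-(((hbp - 275) / 25)^2))
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dtheta * deg) * RC
  list(dLp = dLp, dCp = dCp, dHp = dHp,
       SL = SL, SC = SC, SH = SH, RT = RT,
       kL = kL, kC = kC, kH = kH)
}

#' CIEDE2000 color difference
#'
#' Total color difference under the CIEDE2000 formula, including the
#' lightness/chroma/hue weighting functions `SL`, `SC`, `SH` and the blue
#' rotation term `RT`. With the default parametric weights
#' `kL = kC = kH = 1` (the graphic-arts setting) the result is symmetric in
#' its arguments.
#'
#' @inheritParams delta_e_cielab
#' @param kL,kC,kH positive parametric weighting factors; default 1.
#' @return nonnegative numeric vector.
#' @examples
#' delta_e_ciede2000(lab(50, 2.6772, -79.7751), lab(50, 0, -82.7485)) # 2.0425
#' @export
delta_e_ciede2000 <- function(c1, c2, kL = 1, kC = 1, kH = 1) {
  t <- .ciede2000_terms(c1, c2, kL, kC, kH)
  vL <- t$dLp / (t$kL * t$SL)
  vC <- t$dCp / (t$kC * t$SC)
  vH <- t$dHp / (t$kH * t$SH)
  as.numeric(sqrt(pmax(vL^2 + vC^2 + vH^2 + t$RT * vC * vH, 0)))
}

#' CIEDE2000 chroma term
#'
#' Magnitude of the chroma component of the CIEDE2000 difference,
#' `|dC'| / (kC * SC)`, using the same primed chroma and weighting
#' intermediates as [delta_e_ciede2000()]. This is the package's reading of a
#' "CIEDE2000 chroma difference": it is bounded above by the total difference
#' for the default weights.
#'
#' @inheritParams delta_e_ciede2000
#' @return nonnegative numeric vector.
#' @export
delta_c_ciede2000 <- function(c1, c2, kL = 1, kC = 1, kH = 1) {
  t <- .ciede2000_terms(c1, c2, kL, kC, kH)
  as.numeric(abs(t$dCp) / (t$kC * t$SC))
}

#' sRGB transfer functions
#'
#' `srgb_decode()` maps encoded sRGB values in \[0, 1\] to linear-light
#' values (the piecewise gamma-2.4 law with linear toe); `srgb_encode()` is
#' its inverse.
#'
#' @param x numeric vector/array of encoded (resp. linear) values in \[0, 1\].
#' @return numeric object of the same shape.
#' @export
srgb_decode <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

#' @rdname srgb_decode
#' @export
srgb_encode <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

.xyz_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

.xyz_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' XYZ / CIELAB transforms
#'
#' Converts tristimulus values (Y = 100 for the reference white) to CIELAB
#' and back, using the standard cube-root law with the linear segment near
#' black. The default white point is D65 as rendered by the sRGB matrix, so
#' the white point itself maps to exactly (100, 0, 0).
#'
#' @param xyz n x 3 matrix of tristimulus values (Y = 100 scale).
#' @param white length-3 reference white (same scale).
#' @return n x 3 Lab matrix (resp. XYZ matrix).
#' @export
xyz_to_lab <- function(xyz, white = .d65_white) {
  xyz <- .as_rgb(xyz)
  fx <- .xyz_f(xyz[, 1] / white[1])
  fy <- .xyz_f(xyz[, 2] / white[2])
  fz <- .xyz_f(xyz[, 3] / white[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' @rdname xyz_to_lab
#' @param labm n x 3 matrix of Lab coordinates.
#' @export
lab_to_xyz <- function(labm, white = .d65_white) {
  labm <- .as_lab(labm)
  fy <- (labm[, 1] + 16) / 116
  fx <- fy + labm[, 2] / 500
  fz <- fy - labm[, 3] / 200
  cbind(X = white[1] * .xyz_f_inv(fx),
        Y = white[2] * .xyz_f_inv(fy),
        Z = white[3] * .xyz_f_inv(fz))
}

#' Chromatic adaptation (Bradford)
#'
#' Adapts tristimulus values from one reference white to another with the
#' linear Bradford transform: XYZ are mapped to sharpened cone-like
#' responses, scaled by the ratio of the destination to source white
#' responses, and mapped back.
#'
#' @param xyz n x 3 matrix of tristimulus values.
#' @param from,to length-3 source and destination white points (Y = 100).
#' @return adapted n x 3 XYZ matrix.
#' @export
bradford_adapt <- function(xyz, from, to) {
  xyz <- .as_rgb(xyz)
  cone_src <- as.numeric(.bradford_mat %*% from)
  cone_dst <- as.numeric(.bradford_mat %*% to)
  M <- solve(.bradford_mat) %*% diag(cone_dst / cone_src) %*% .bradford_mat
  out <- xyz %*% t(M)
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' Convert sRGB to CIELAB
#'
#' Decodes the sRGB transfer function, applies the fixed sRGB-to-XYZ matrix
#' (D65 white, 2-degree observer), and converts to CIELAB. Inputs are either
#' values in \[0, 1\] (default) or integers at a declared bit depth.
#'
#' @param rgb n x 3 matrix (or length-3 vector) of sRGB values.
#' @param bits `NULL` for \[0, 1\] input, or 8/16 for integer input; integer
#'   values outside `0..2^bits - 1` are rejected.
#' @return n x 3 Lab matrix.
#' @examples
#' srgb_to_lab(c(255, 255, 255), bits = 8) # (100, 0, 0)
#' @export
srgb_to_lab <- function(rgb, bits = NULL) {
  rgb <- .as_rgb(rgb)
  if (!is.null(bits)) {
    if (!bits %in% c(8, 16)) stop("bits must be 8 or 16")
    top <- 2^bits - 1
    if (any(rgb < 0 | rgb > top))
      stop(sprintf("RGB values out of range for %d-bit input (0..%d)", bits, top))
    rgb <- rgb / top
  } else if (any(rgb < -1e-9 | rgb > 1 + 1e-9)) {
    stop("RGB values must lie in [0, 1] (or pass an integer bit depth)")
  }
  lin <- srgb_decode(rgb)
  xyz <- lin %*% t(.srgb_to_xyz_mat) * 100
  xyz_to_lab(xyz)
}

#' Convert CIELAB to sRGB
#'
#' Inverse of [srgb_to_lab()]. Colors outside the sRGB gamut are clipped to
#' \[0, 1\] per channel and flagged in the `"clipped"` attribute (one logical
#' per color); clipping is signalled, never fatal.
#'
#' @param labm n x 3 matrix (or length-3 vector) of Lab coordinates.
#' @return n x 3 matrix of encoded sRGB values in \[0, 1\], with attribute
#'   `clipped`.
#' @export
lab_to_srgb <- function(labm) {
  labm <- .as_lab(labm)
  xyz <- lab_to_xyz(labm) / 100
  lin <- xyz %*% t(.xyz_to_srgb_mat)
  clipped <- unname(apply(lin < -1e-7 | lin > 1 + 1e-7, 1, any))
  lin <- pmin(pmax(lin, 0), 1)
  out <- srgb_encode(lin)
  colnames(out) <- c("R", "G", "B")
  attr(out, "clipped") <- clipped
  out
}
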