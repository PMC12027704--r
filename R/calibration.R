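# Gray-card white balance and exposure calibration.
#
# White balance is modeled as per-channel multiplicative gains in linear
# RGB (a von Kries-style sensor-domain correction), anchored to a neutral
# mid-gray reference (L* = 50, a* = 0, b* = 0). Gains are normalized to the
# green channel, the camera convention.

# Relative luminance of the L* = 50 mid-gray.
.y_mid_gray <- ((50 + 16) / 116)^3

#' White-balance gains
#'
#' Per-channel multiplicative gains in linear RGB, normalized so the green
#' gain is 1.
#'
#' @param gr,gg,gb positive gains for the red, green, blue channels.
#' @return object of class `wb_gains`: named numeric length 3.
#' @export
wb_gains <- function(gr, gg, gb) {
  g <- c(r = gr, g = gg, b = gb)
  if (any(!is.finite(g)) || any(g <= 0)) stop("gains must be positive")
  structure(g / g[2], class = "wb_gains")
}

#' @export
print.wb_gains <- function(x, ...) {
  cat(sprintf("<wb_gains r=%.4f g=%.4f b=%.4f>\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Gray reference region
#'
#' A region of an image known to show a neutral mid-gray target
#' (L* = 50, a* = 0, b* = 0), given either as a convex quadrilateral
#' (4 x 2 corner matrix, as in [patch_region()]) or a logical pixel mask.
#'
#' @param region 4 x 2 polygon matrix or logical H x W mask.
#' @return object of class `gray_reference`.
#' @export
gray_reference <- function(region) {
  if (is.matrix(region) && is.logical(region)) {
    structure(list(mask = region, polygon = NULL,
                   target = lab(50, 0, 0)), class = "gray_reference")
  } else {
    poly <- matrix(as.numeric(region), ncol = 2)
    if (nrow(poly) != 4) stop("gray region polygon must have 4 corners")
    structure(list(mask = NULL, polygon = poly,
                   target = lab(50, 0, 0)), class = "gray_reference")
  }
}

# Encoded pixels (n x 3) inside a gray reference region.
.gray_pixels <- function(image, gray) {
  image <- .check_image(image)
  if (!is.null(gray$mask)) {
    if (!all(dim(gray$mask) == dim(image)[1:2]))
      stop("gray mask dimensions do not match the image")
    sel <- which(gray$mask)
    if (length(sel) == 0) stop("empty gray reference region")
    cbind(image[, , 1][sel], image[, , 2][sel], image[, , 3][sel])
  } else {
    H <- dim(image)[1]; W <- dim(image)[2]
    xr <- range(gray$polygon[, 1]); yr <- range(gray$polygon[, 2])
    c0 <- max(1, floor(xr[1] + 0.5)); c1 <- min(W, ceiling(xr[2] + 0.5))
    r0 <- max(1, floor(yr[1] + 0.5)); r1 <- min(H, ceiling(yr[2] + 0.5))
    if (c1 < c0 || r1 < r0) stop("empty gray reference region")
    grid <- expand.grid(y = r0:r1, x = c0:c1)
    inside <- .in_convex_poly(cbind(grid$x - 0.5, grid$y - 0.5), gray$polygon)
    if (!any(inside)) stop("empty gray reference region")
    sel <- grid[inside, ]
    cbind(image[cbind(sel$y, sel$x, 1)],
          image[cbind(sel$y, sel$x, 2)],
          image[cbind(sel$y, sel$x, 3)])
  }
}

#' Estimate white-balance gains from a gray reference
#'
#' Decodes the region to linear RGB, takes a two-sided trimmed mean per
#' channel, and returns the reciprocals normalized to green = 1: the gains
#' that map the region back to neutral. The reference is rejected as
#' unusable when a channel mean is nonpositive or when more than half the
#' region is clipped at saturation.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param gray a `gray_reference`.
#' @param trim two-sided trim fraction for the channel means; default 0.1.
#' @return a `wb_gains` object.
#' @export
estimate_gains <- function(image, gray, trim = 0.1) {
  stopifnot(inherits(gray, "gray_reference"))
  px <- .gray_pixels(image, gray)
  sat <- rowSums(px >= 1 - 1e-3) > 0
  if (mean(sat) > 0.5)
    stop("gray reference unusable: more than half the region is clipped at saturation")
  lin <- srgb_decode(px)
  m <- vapply(1:3, function(ch) mean(lin[, ch], trim = trim), numeric(1))
  if (any(m <= 0)) stop("gray reference unusable: nonpositive channel mean")
  g <- 1 / m
  wb_gains(g[1], g[2], g[3])
}

#' Apply a white-balance (and optional exposure) correction
#'
#' Linearizes the image, multiplies each channel by its gain, optionally
#' rescales all channels uniformly so the gray reference's mean relative
#' luminance equals that of L* = 50, re-encodes, and clips to \[0, 1\].
#' The gray reference may live in the image being corrected (a card in the
#' frame) or in a separate reference capture taken under the same
#' conditions (`gray_image`), the usual post-production workflow. The
#' fraction of channel samples clipped is attached as the
#' `clipping_fraction` attribute; a fraction above 10% raises a warning
#' (never an error).
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param gains a `wb_gains` object.
#' @param exposure_to_gray logical; when `TRUE`, `gray` must be given.
#' @param gray a `gray_reference` (required for exposure anchoring).
#' @param gray_image image containing the gray reference; defaults to
#'   `image` itself.
#' @return corrected H x W x 3 array with attribute `clipping_fraction`.
#' @export
apply_correction <- function(image, gains, exposure_to_gray = FALSE,
                             gray = NULL, gray_image = image) {
  image <- .check_image(image)
  stopifnot(inherits(gains, "wb_gains"))
  lin <- srgb_decode(image)
  for (ch in 1:3) lin[, , ch] <- lin[, , ch] * gains[ch]
  if (exposure_to_gray) {
    if (is.null(gray)) stop("exposure_to_gray requires a gray reference")
    # luminance of the gray region after channel gains
    px <- sweep(srgb_decode(.gray_pixels(gray_image, gray)), 2,
                as.numeric(gains), "*")
    ylum <- mean(px %*% c(0.2126, 0.7152, 0.0722))
    if (ylum <= 0) stop("gray region has zero luminance")
    lin <- lin * (.y_mid_gray / ylum)
  }
  clipped <- mean(lin < 0 | lin > 1)
  out <- srgb_encode(pmin(pmax(lin, 0), 1))
  attr(out, "clipping_fraction") <- clipped
  if (clipped > 0.1)
    warning(sprintf("correction clipped %.1f%% of channel samples",
                    100 * clipped))
  out
}

# Conventional third-stop shutter ladder, 1/8000 s to 1 s.
.shutter_ladder <- local({
  denoms <- c(8000, 6400, 5000, 4000, 3200, 2500, 2000, 1600, 1250, 1000,
              800, 640, 500, 400, 320, 250, 200, 160, 125, 100, 80, 64, 50,
              40, 32, 25, 20, 16, 13, 10, 8, 6, 5, 4, 3, 2.5, 2, 1.6, 1.3, 1)
  1 / denoms
})

#' Capture settings
#'
#' White-balance color temperature (K), sensor sensitivity (ISO) and
#' exposure time (s). Aperture is not a parameter: smartphone cameras have
#' fixed apertures.
#'
#' @param cct_K,iso,shutter_s positive numerics.
#' @return object of class `capture_settings`.
#' @export
capture_settings <- function(cct_K, iso, shutter_s) {
  if (any(c(cct_K, iso, shutter_s) <= 0)) stop("settings must be positive")
  structure(list(cct_K = cct_K, iso = iso, shutter_s = shutter_s),
            class = "capture_settings")
}

#' @export
print.capture_settings <- function(x, ...) {
  shows <- if (x$shutter_s < 1) sprintf("1/%g s", round(1 / x$shutter_s)) else
    sprintf("%g s", x$shutter_s)
  cat(sprintf("<capture_settings CCT=%.0f K, ISO %g, shutter %s>\n",
              x$cct_K, x$iso, shows))
  invisible(x)
}

#' Recommend manual camera settings for a light source
#'
#' The manual-settings guideline: set the white balance to the source's
#' correlated color temperature, keep the lowest available ISO (low ISO
#' minimizes noise), and scale the shutter time from the baseline in inverse
#' proportion to the measured mid-gray luminance, rounding to the nearest
#' standard third-stop value. With a dermoscope-class LED at 7080 K and the
#' nominal mid-gray luminance this reproduces the published guideline
#' (CCT 7080 K, ISO 48, 1/800 s).
#'
#' @param spd a `spectral_curve` of the light source.
#' @param gray_luminance measured relative luminance of a mid-gray target
#'   under the source, on the same scale as `base_gray_luminance`.
#' @param base baseline `capture_settings`; default ISO 48, 1/800 s.
#' @param base_gray_luminance luminance at which `base` exposes mid-gray
#'   correctly; defaults to the relative luminance of L* = 50.
#' @return a `capture_settings` with the recommended values.
#' @export
recommend_settings <- function(spd, gray_luminance,
                               base = capture_settings(5500, 48, 1 / 800),
                               base_gray_luminance = .y_mid_gray) {
  stopifnot(inherits(spd, "spectral_curve"), inherits(base, "capture_settings"))
  if (gray_luminance <= 0) stop("gray luminance must be positive")
  ct <- cct(spd)
  shutter <- base$shutter_s * base_gray_luminance / gray_luminance
  rounded <- .shutter_ladder[which.min(abs(log(.shutter_ladder / shutter)))]
  capture_settings(ct$cct, base$iso, rounded)
}
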