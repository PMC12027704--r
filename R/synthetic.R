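# Synthetic inputs: chart renders under parameterized camera distortions,
# gray-card scenes, and analytic spectra. Everything is seeded explicitly;
# no global random state leaks in or out.

# Run fn with a local RNG seeded by `seed` (NULL = leave RNG alone).
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Camera distortion model
#'
#' Ground-truth distortion applied by the synthetic renderer, standing in
#' for a device's internal processing: per-channel multiplicative gains in
#' linear RGB (an un-neutralized illuminant cast / wrong white balance), a
#' gamma exponent multiplier applied in the encoded domain, and additive
#' Gaussian noise in the encoded 8-bit domain.
#'
#' @param gains length-3 positive channel gains (linear domain); default
#'   identity.
#' @param gamma_error encoded-domain exponent multiplier in (0.5, 2);
#'   1 = none.
#' @param noise_sigma additive Gaussian sigma in 8-bit counts; >= 0.
#' @param seed integer seed for the noise, or `NULL`.
#' @return object of class `camera_distortion`.
#' @export
camera_distortion <- function(gains = c(1, 1, 1), gamma_error = 1,
                              noise_sigma = 0, seed = NULL) {
  gains <- as.numeric(gains)
  if (length(gains) != 3 || any(gains <= 0)) stop("gains must be 3 positive values")
  if (gamma_error <= 0.5 || gamma_error >= 2)
    stop("gamma_error must lie in (0.5, 2)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(gains = gains, gamma_error = gamma_error,
                 noise_sigma = noise_sigma, seed = seed),
            class = "camera_distortion")
}

# Distort encoded sRGB colors (n x 3): linearize, apply channel gains,
# clip, re-encode, apply the gamma error. Returns encoded colors plus a
# per-color clipped flag.
.distort_colors <- function(enc, distortion) {
  lin <- srgb_decode(enc)
  lin <- sweep(lin, 2, distortion$gains, "*")
  clipped <- apply(lin < 0 | lin > 1, 1, any)
  enc2 <- srgb_encode(pmin(pmax(lin, 0), 1))^distortion$gamma_error
  list(enc = enc2, clipped = clipped)
}

.quantize <- function(x, bits) {
  top <- 2^bits - 1
  round(pmin(pmax(x, 0), 1) * top) / top
}

#' Render a synthetic chart image
#'
#' Renders the 24-patch chart on a dark background: reference CIELAB to
#' encoded sRGB, linearized, multiplied by the distortion gains (the
#' simulated un-balanced capture), re-encoded with the gamma error, then
#' seeded Gaussian noise is added in the encoded domain and the image is
#' quantized to the requested bit depth. The returned ground truth holds
#' the exact pre-noise patch colors (with per-patch gamut-clip flags) and
#' the exact patch geometry.
#'
#' @param chart a `reference_chart`; default the packaged classic values.
#' @param distortion a `camera_distortion`.
#' @param patch_px patch side in pixels (>= 8).
#' @param border_px border width between patches in pixels.
#' @param corners optional 4 x 2 destination corners (TL, TR, BR, BL): the
#'   chart is rendered under the homography they define on a canvas sized to
#'   contain them.
#' @param bits output bit depth (8 or 16).
#' @param background encoded background/border gray level.
#' @return list with `image` (H x W x 3), `truth` (data.frame: `index`,
#'   `name`, pre-noise `L`, `a`, `b`, `clipped`), `regions` (list of
#'   `patch_region`), and `distortion`.
#' @export
render_chart <- function(chart = reference_chart(),
                         distortion = camera_distortion(),
                         patch_px = 32, border_px = 8, corners = NULL,
                         bits = 8, background = 0.08) {
  stopifnot(inherits(chart, "reference_chart"),
            inherits(distortion, "camera_distortion"))
  if (patch_px < 8) stop("patch_px must be >= 8")
  if (!bits %in% c(8, 16)) stop("bits must be 8 or 16")
  enc_ref <- lab_to_srgb(as.matrix(chart[, c("L_ref", "a_ref", "b_ref")]))
  dist <- .distort_colors(enc_ref, distortion)
  bg <- .distort_colors(matrix(background, 1, 3), distortion)$enc
  truth_lab <- srgb_to_lab(dist$enc)
  truth <- data.frame(index = chart$index, name = chart$name,
                      L = truth_lab[, 1], a = truth_lab[, 2],
                      b = truth_lab[, 3],
                      clipped = attr(enc_ref, "clipped") | dist$clipped,
                      stringsAsFactors = FALSE)

  if (is.null(corners)) {
    W <- .patch_cols * patch_px + (.patch_cols + 1) * border_px
    H <- .patch_rows * patch_px + (.patch_rows + 1) * border_px
    img <- array(rep(bg, each = H * W), c(H, W, 3))
    regions <- vector("list", 24)
    for (r in 1:.patch_rows) for (c in 1:.patch_cols) {
      idx <- (r - 1) * .patch_cols + c
      x0 <- border_px + (c - 1) * (patch_px + border_px)
      y0 <- border_px + (r - 1) * (patch_px + border_px)
      img[(y0 + 1):(y0 + patch_px), (x0 + 1):(x0 + patch_px), ] <-
        rep(dist$enc[idx, ], each = patch_px^2)
      regions[[idx]] <- patch_region(idx, matrix(
        c(x0, y0, x0 + patch_px, y0, x0 + patch_px, y0 + patch_px,
          x0, y0 + patch_px), ncol = 2, byrow = TRUE))
    }
  } else {
    corners <- matrix(as.numeric(corners), ncol = 2)
    W <- ceiling(max(corners[, 1])); H <- ceiling(max(corners[, 2]))
    Hm <- .homography_from_corners(corners)
    Hinv <- solve(Hm)
    grid <- expand.grid(y = seq_len(H), x = seq_len(W))
    uv <- .apply_homography(Hinv, cbind(grid$x - 0.5, grid$y - 0.5))
    bf <- border_px / patch_px
    Wu <- .patch_cols + (.patch_cols + 1) * bf
    Hu <- .patch_rows + (.patch_rows + 1) * bf
    xu <- uv[, 1] * Wu; yu <- uv[, 2] * Hu
    inside <- uv[, 1] >= 0 & uv[, 1] <= 1 & uv[, 2] >= 0 & uv[, 2] <= 1
    colc <- floor((xu - bf) / (1 + bf)) + 1
    rowc <- floor((yu - bf) / (1 + bf)) + 1
    inpx <- (xu - bf) %% (1 + bf) < 1 & (yu - bf) %% (1 + bf) < 1 &
      colc >= 1 & colc <= 6 & rowc >= 1 & rowc <= 4 & xu >= bf & yu >= bf
    pix <- matrix(rep(bg, each = H * W), H * W, 3)
    hit <- inside & inpx
    pidx <- (rowc - 1) * 6 + colc
    pix[hit, ] <- dist$enc[pidx[hit], ]
    pix[!inside, ] <- rep(bg, each = sum(!inside))
    img <- array(pix, c(H, W, 3))
    polys <- .canonical_polys(bf)
    regions <- lapply(1:24, function(i)
      patch_region(i, .apply_homography(Hm, polys[[i]])))
  }

  if (distortion$noise_sigma > 0) {
    img <- .with_seed(distortion$seed, function()
      img + array(stats::rnorm(length(img), sd = distortion$noise_sigma / 255),
                  dim(img)))
  }
  img <- .quantize(img, bits)
  list(image = img, truth = truth, regions = regions, distortion = distortion)
}

#' Render single-patch captures
#'
#' Renders one uniform frame per requested patch, passed through the same
#' distortion pipeline as [render_chart()] -- the dermoscope-style
#' acquisition where each chart patch fills its own image.
#'
#' @inheritParams render_chart
#' @param indices patch indices to render (default all 24).
#' @param size frame side in pixels.
#' @return list of `list(index =, image =)` entries, ready for
#'   [assemble_single_patch_table()].
#' @export
render_single_patches <- function(chart = reference_chart(),
                                  distortion = camera_distortion(),
                                  indices = 1:24, size = 48, bits = 8) {
  stopifnot(inherits(chart, "reference_chart"))
  enc_ref <- lab_to_srgb(as.matrix(chart[, c("L_ref", "a_ref", "b_ref")]))
  dist <- .distort_colors(enc_ref, distortion)
  frames <- lapply(indices, function(i) {
    img <- array(rep(dist$enc[i, ], each = size^2), c(size, size, 3))
    if (distortion$noise_sigma > 0) {
      img <- .with_seed(
        if (is.null(distortion$seed)) NULL else distortion$seed + i,
        function() img + array(stats::rnorm(length(img),
                                            sd = distortion$noise_sigma / 255),
                               dim(img)))
    }
    list(index = i, image = .quantize(img, bits))
  })
  frames
}

#' Render a synthetic gray-card scene
#'
#' A uniform neutral mid-gray region (L* = 50, a* = 0, b* = 0) embedded in a
#' textured background of seeded random blocks, the whole scene passed
#' through the distortion pipeline. Emulates a gray reference sheet
#' partially covering the field of view.
#'
#' @param distortion a `camera_distortion`.
#' @param width,height canvas size in pixels.
#' @param gray_frac side fraction of the centered gray rectangle.
#' @param bits output bit depth.
#' @return list with `image`, `gray` (a `gray_reference` whose polygon is
#'   the true gray rectangle), and `distortion`.
#' @export
render_gray_scene <- function(distortion = camera_distortion(),
                              width = 160, height = 120, gray_frac = 0.4,
                              bits = 8) {
  stopifnot(inherits(distortion, "camera_distortion"))
  gray_enc <- lab_to_srgb(lab(50, 0, 0))
  block <- 16
  nbx <- ceiling(width / block); nby <- ceiling(height / block)
  img <- .with_seed(distortion$seed, function() {
    base <- array(0, c(height, width, 3))
    cols <- matrix(stats::runif(nbx * nby * 3, 0.15, 0.85), ncol = 3)
    k <- 1
    for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
      ys <- ((by - 1) * block + 1):min(by * block, height)
      xs <- ((bx - 1) * block + 1):min(bx * block, width)
      base[ys, xs, ] <- rep(cols[k, ], each = length(ys) * length(xs))
      k <- k + 1
    }
    base
  })
  gw <- round(width * gray_frac); gh <- round(height * gray_frac)
  x0 <- floor((width - gw) / 2); y0 <- floor((height - gh) / 2)
  img[(y0 + 1):(y0 + gh), (x0 + 1):(x0 + gw), ] <-
    rep(gray_enc, each = gh * gw)
  pix <- .distort_colors(matrix(img, height * width, 3), distortion)$enc
  img <- array(pix, c(height, width, 3))
  if (distortion$noise_sigma > 0) {
    img <- .with_seed(
      if (is.null(distortion$seed)) NULL else distortion$seed + 1L,
      function() img + array(stats::rnorm(length(img),
                                          sd = distortion$noise_sigma / 255),
                             dim(img)))
  }
  img <- .quantize(img, bits)
  poly <- matrix(c(x0, y0, x0 + gw, y0, x0 + gw, y0 + gh, x0, y0 + gh),
                 ncol = 2, byrow = TRUE)
  list(image = img, gray = gray_reference(poly), distortion = distortion)
}

#' Analytic spectra: Planckian, daylight, LED
#'
#' `planckian_spd()` evaluates Planck's law for a blackbody at `T` kelvin;
#' `daylight_spd()` synthesizes the CIE daylight illuminant at `T` from the
#' packaged S0/S1/S2 component vectors; `led_spd()` sums Gaussian emission
#' bands (center, full width at half maximum, amplitude) -- the usual
#' phosphor-LED stand-in. All are evaluated analytically on the canonical
#' 5 nm grid and scaled to a maximum of 1.
#'
#' @param T temperature in kelvin; Planckian accepts 2000-10000 K, daylight
#'   4000-25000 K.
#' @return a `spectral_curve`.
#' @examples
#' cct(planckian_spd(6500))$cct   # ~6500
#' @export
planckian_spd <- function(T) {
  if (T < 2000 || T > 10000) stop("Planckian generator accepts 2000-10000 K")
  spectral_curve(.spd_grid, .planck_values(T),
                 label = sprintf("planckian_%dK", round(T)))
}

#' @rdname planckian_spd
#' @export
daylight_spd <- function(T) {
  spectral_curve(.spd_grid, .daylight_values(T),
                 label = sprintf("daylight_%dK", round(T)))
}

#' @rdname planckian_spd
#' @param peaks list of `c(center_nm, fwhm_nm, amplitude)` triples; centers
#'   must lie in 380-780 nm.
#' @export
led_spd <- function(peaks) {
  if (!length(peaks)) stop("led_spd needs at least one peak")
  v <- numeric(length(.spd_grid))
  for (p in peaks) {
    p <- as.numeric(p)
    if (length(p) != 3) stop("each peak is c(center, fwhm, amplitude)")
    if (p[1] < 380 || p[1] > 780) stop("peak center outside 380-780 nm")
    if (p[2] <= 0 || p[3] < 0) stop("peak fwhm must be > 0 and amplitude >= 0")
    sigma <- p[2] / (2 * sqrt(2 * log(2)))
    v <- v + p[3] * exp(-0.5 * ((.spd_grid - p[1]) / sigma)^2)
  }
  if (max(v) > 0) v <- v / max(v)
  spectral_curve(.spd_grid, v, label = "led")
}

#' Dermoscope-style LED spectrum at a requested CCT
#'
#' Three-band LED model of dermoscope illumination: a narrow blue pump at
#' 460 nm, a broad phosphor band at 545 nm, and a reduced red shoulder at
#' 630 nm (at 35% of the phosphor amplitude) -- peaks in the blue and green
#' with weak red output. The phosphor amplitude is solved (by root finding
#' on the package's own CCT computation) so the source hits the requested
#' correlated color temperature; the default reproduces the 7080 K
#' dermoscope-class source of the manual-settings guideline.
#'
#' @param target_cct desired CCT in kelvin (5000-10000).
#' @return a `spectral_curve`.
#' @export
dermoscope_led_spd <- function(target_cct = 7080) {
  if (target_cct < 5000 || target_cct > 10000)
    stop("dermoscope LED model covers 5000-10000 K")
  make <- function(a) led_spd(list(c(460, 25, 1), c(545, 90, a),
                                   c(630, 90, 0.35 * a)))
  f <- function(a) cct(make(a))$cct - target_cct
  a <- stats::uniroot(f, c(0.2, 3), tol = 1e-5)$root
  out <- make(a)
  out$label <- sprintf("dermoscope_led_%dK", round(target_cct))
  out
}
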