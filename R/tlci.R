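# Television lighting consistency scoring through a model camera/display
# chain.
#
# The score answers a different question than the CRI: not how colors look
# to an observer, but how faithfully a television-style camera plus display
# reproduces them under the source versus under a reference illuminant. The
# chain implemented here is the package's own documented model (the
# published standard's exact camera data is not shipped): Gaussian R/G/B
# camera spectral sensitivities, per-channel white balance against the
# illuminant, a fixed 3x3 linear matrix to display primaries (fitted once,
# colorimetrically, under D65 with white preservation), clipping to the
# display gamut, and CIELAB on the display. The 24 chart patches are imaged
# under the test source and under the reference illuminant at the test CCT
# through the *same* chain, so a source identical to its reference scores
# exactly 100.

# Model camera spectral sensitivities on the canonical grid.
.camera_sensitivities <- function() {
  .cached("camera_sens", function() {
    g <- function(mu, sigma) exp(-0.5 * ((.spd_grid - mu) / sigma)^2)
    cbind(R = g(600, 33), G = g(535, 35), B = g(460, 30))
  })
}

# Reference illuminant for the television score: Planckian below 4000 K,
# daylight above 5000 K, and a linear blend of the two (each normalized at
# 560 nm) across the 4000-5000 K band -- the midpoint convention at 4500 K.
# Within the blend band the nominal temperature is solved so the blended
# curve's own computed CCT equals the requested one (the reference map is a
# fixed point of the CCT computation, so a source identical to its
# reference is reproduced exactly).
.tlci_blend <- function(Tn) {
  at560 <- function(v) v / v[.spd_grid == 560]
  w <- (Tn - 4000) / 1000
  v <- (1 - w) * at560(.planck_values(Tn)) + w * at560(.daylight_values(Tn))
  v / max(v)
}

.tlci_reference_values <- function(T) {
  if (T <= 4000) return(.planck_values(T))
  if (T >= 5000) return(.daylight_values(min(T, 25000)))
  curve_cct <- function(Tn)
    cct(spectral_curve(.spd_grid, .tlci_blend(Tn)))$cct - T
  lo <- curve_cct(4000 + 1e-6); hi <- curve_cct(5000 - 1e-6)
  if (lo > 0) return(.planck_values(T))
  if (hi < 0) return(.daylight_values(T))
  Tn <- stats::uniroot(curve_cct, c(4000 + 1e-6, 5000 - 1e-6), tol = 1e-4)$root
  .tlci_blend(Tn)
}

# Rec. 709 / sRGB primaries share the same RGB<->XYZ matrices.
.display_white <- function() as.numeric(.srgb_to_xyz_mat %*% c(1, 1, 1)) * 100

# Balanced camera RGB for each patch reflectance under an illuminant.
.camera_rgb <- function(illum) {
  S <- .camera_sensitivities()
  refl <- .chart_reflectances()
  raw <- t(crossprod(S, refl * illum))        # patches x 3
  white <- as.numeric(crossprod(S, illum))
  sweep(raw, 2, white, "/")
}

# Fixed camera color matrix: least-squares map from balanced camera RGB to
# linear display RGB for the 24 patches under D65, rows renormalized to
# preserve white. A property of the model camera, computed once.
.camera_matrix <- function() {
  .cached("camera_matrix", function() {
    illum <- .d65_illuminant()
    cam <- .camera_rgb(illum)
    xyz <- .tristimulus(.chart_reflectances() * illum, normalize = illum)
    target <- (xyz / 100) %*% t(.xyz_to_srgb_mat)
    M <- t(qr.solve(cam, target))             # 3 x 3
    M / rowSums(M)
  })
}

# Display-rendered Lab of the 24 patches under an illuminant, through the
# model camera chain.
.chain_lab <- function(illum) {
  lin <- .camera_rgb(illum) %*% t(.camera_matrix())
  lin <- pmin(pmax(lin, 0), 1)
  xyz <- lin %*% t(.srgb_to_xyz_mat) * 100
  xyz_to_lab(xyz, white = .display_white())
}

#' Television lighting consistency score of a light source
#'
#' Images the 24 reference chart patches through the package's model
#' camera/display chain under the test source and under the reference
#' illuminant at the test source's correlated color temperature, and maps
#' the mean CIEDE2000 difference between the two renderings to a 0-100
#' quality score `Qa`: `Qa = 100 / (1 + (mean dE00 / 3.5)^2)`. The scaling
#' constants are the package's own calibration of the score (documented in
#' the methods vignette); the analytic limit is exact: a test source equal
#' to its reference scores 100.
#'
#' @param spd a `spectral_curve`.
#' @return list with `qa`, `mean_de00`, `cct`, `duv`, `warnings`.
#' @examples
#' tlci(daylight_spd(5600))$qa # 100
#' @export
tlci <- function(spd) {
  stopifnot(inherits(spd, "spectral_curve"))
  test <- .spd_values(spd)
  ct <- cct(spd)
  ref <- .tlci_reference_values(ct$cct)
  lab_t <- .chain_lab(test)
  lab_r <- .chain_lab(ref)
  de <- mean(delta_e_ciede2000(lab_t, lab_r))
  qa <- 100 / (1 + (de / 3.5)^2)
  list(qa = qa, mean_de00 = de, cct = ct$cct, duv = ct$duv,
       warnings = ct$warnings)
}

#' Full light-quality report for a source
#'
#' Bundles correlated color temperature, Duv, the color rendering index
#' (general `Ra` and special `R1..R14`), and the television lighting
#' consistency score for one spectral power distribution.
#'
#' @param spd a `spectral_curve`.
#' @return object of class `light_quality_report`: list with `label`,
#'   `cct_K`, `duv`, `ra`, `ri`, `tlci`, `warnings`.
#' @examples
#' light_quality_report(planckian_spd(3000))
#' @export
light_quality_report <- function(spd) {
  stopifnot(inherits(spd, "spectral_curve"))
  cr <- cri(spd)
  tl <- tlci(spd)
  structure(list(label = spd$label, cct_K = cr$cct, duv = cr$duv,
                 ra = cr$ra, ri = cr$ri, tlci = tl$qa,
                 warnings = union(cr$warnings, tl$warnings)),
            class = "light_quality_report")
}

#' @export
print.light_quality_report <- function(x, ...) {
  cat(sprintf("Light quality report%s\n",
              if (nzchar(x$label)) paste0(" -- ", x$label) else ""))
  cat(sprintf("  CCT  %.0f K   (Duv %+.4f)\n", x$cct_K, x$duv))
  cat(sprintf("  CRI  Ra %.2f\n", x$ra))
  cat(sprintf("  TLCI Qa %.2f\n", x$tlci))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a light-quality report to JSON
#'
#' @param report a `light_quality_report`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_light_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "light_quality_report"))
  obj <- list(label = report$label, cct_K = report$cct_K, duv = report$duv,
              ra = report$ra, ri = as.numeric(report$ri),
              tlci = report$tlci, warnings = as.character(report$warnings))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
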