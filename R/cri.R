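# Color rendering index, following the CIE 13.3 test-sample method.
#
# Reference illuminant: a Planckian radiator at the test source's CCT below
# 5000 K, the CIE daylight illuminant at the test CCT at or above 5000 K.
# The 14 test-color samples are rendered under test and reference, the test
# renderings are chromatically adapted to the reference with the von Kries
# correction in the 1960 uv diagram, color differences are taken in U*V*W*,
# and Ri = 100 - 4.6 dE_i with Ra the mean of R1..R8.
#
# The test-color reflectances packaged here are synthetic stand-ins (smooth
# metamers of Lab anchors spanning the official set's character), not the
# official CIE 13.3 tabulation; see the methods vignette.

# von Kries c/d adaptation helpers (1960 uv diagram)
.vk_c <- function(u, v) (4 - u - 10 * v) / v
.vk_d <- function(u, v) (1.708 * v + 0.404 - 1.481 * u) / v

#' Color rendering index of a light source
#'
#' General color rendering index `Ra` and the 14 special indices `Ri` of a
#' source, computed from its spectral power distribution by the
#' test-sample method: each sample is rendered under the source and under
#' the reference illuminant at the source's correlated color temperature
#' (Planckian below 5000 K, daylight at or above), with von Kries chromatic
#' adaptation and U*V*W* color differences. `Ra` is the mean of the first
#' eight special indices; a source identical to its reference scores 100.
#'
#' @param spd a `spectral_curve`.
#' @return list with `ra`, `ri` (length 14), `cct`, `duv`, `warnings`.
#' @examples
#' cri(planckian_spd(3000))$ra # 100
#' @export
cri <- function(spd) {
  stopifnot(inherits(spd, "spectral_curve"))
  test <- .spd_values(spd)
  ct <- cct(spd)
  ref <- .cri_reference_values(ct$cct)
  refl <- .tcs_reflectances()

  uvw_under <- function(illum) {
    xyz_i <- .tristimulus(illum, normalize = illum)
    uv_i <- .xyz_to_uv(xyz_i)
    xyz_s <- .tristimulus(refl * illum, normalize = illum)
    uv_s <- .xyz_to_uv(xyz_s)
    list(uv_illum = as.numeric(uv_i), uv = uv_s, Y = xyz_s[, 2])
  }
  tst <- uvw_under(test)
  rf <- uvw_under(ref)

  # adapt test-rendered chromaticities to the reference adaptation state
  ck <- .vk_c(tst$uv_illum[1], tst$uv_illum[2])
  dk <- .vk_d(tst$uv_illum[1], tst$uv_illum[2])
  cr <- .vk_c(rf$uv_illum[1], rf$uv_illum[2])
  dr <- .vk_d(rf$uv_illum[1], rf$uv_illum[2])
  ci <- .vk_c(tst$uv[, 1], tst$uv[, 2])
  di <- .vk_d(tst$uv[, 1], tst$uv[, 2])
  denom <- 16.518 + 1.481 * (cr / ck) * ci - (dr / dk) * di
  u_ad <- (10.872 + 0.404 * (cr / ck) * ci - 4 * (dr / dk) * di) / denom
  v_ad <- 5.520 / denom

  uv_ref_illum <- rf$uv_illum
  ustar <- function(W, u) 13 * W * (u - uv_ref_illum[1])
  vstar <- function(W, v) 13 * W * (v - uv_ref_illum[2])
  W_t <- 25 * tst$Y^(1 / 3) - 17
  W_r <- 25 * rf$Y^(1 / 3) - 17
  dE <- sqrt((W_r - W_t)^2 +
             (ustar(W_r, rf$uv[, 1]) - ustar(W_t, u_ad))^2 +
             (vstar(W_r, rf$uv[, 2]) - vstar(W_t, v_ad))^2)
  ri <- 100 - 4.6 * dE
  list(ra = mean(ri[1:8]), ri = ri, cct = ct$cct, duv = ct$duv,
       warnings = ct$warnings)
}

# Reference illuminant spectrum for the CRI at a given CCT.
.cri_reference_values <- function(T) {
  if (T < 5000) .planck_values(T) else .daylight_values(min(T, 25000))
}
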