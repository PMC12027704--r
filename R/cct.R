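# Correlated color temperature by Robertson's isotemperature-line method.
#
# The Planckian locus is tabulated densely in reciprocal temperature (1
# mired steps over 10-600 mired, i.e. about 1667 K to 100000 K) in the CIE
# 1960 uv diagram, with isotemperature lines normal to the locus. The CCT of
# a chromaticity is found from the sign change of its signed distance to
# consecutive isotemperature lines, interpolating in reciprocal temperature;
# Duv is the distance to the locus, signed positive above it (v greater than
# the locus).

.robertson_table <- function() {
  .cached("robertson", function() {
    mired <- seq(10, 600, by = 1)
    uv <- t(vapply(mired, function(m) {
      xyz <- .tristimulus(.planck_values(1e6 / m))
      as.numeric(.xyz_to_uv(xyz))
    }, numeric(2)))
    # tangent along the locus by central differences in mired
    du <- c(uv[2, 1] - uv[1, 1], (uv[-(1:2), 1] - uv[1:(nrow(uv) - 2), 1]) / 2,
            uv[nrow(uv), 1] - uv[nrow(uv) - 1, 1])
    dv <- c(uv[2, 2] - uv[1, 2], (uv[-(1:2), 2] - uv[1:(nrow(uv) - 2), 2]) / 2,
            uv[nrow(uv), 2] - uv[nrow(uv) - 1, 2])
    # isotemperature line slope: normal to the tangent
    slope <- -du / dv
    list(mired = mired, u = uv[, 1], v = uv[, 2], slope = slope)
  })
}

#' Correlated color temperature and Duv of a light source
#'
#' Computes tristimulus values of the source through the 2-degree
#' color-matching functions, its chromaticity in the CIE 1960 uv diagram,
#' and the correlated color temperature as the Planckian radiator nearest in
#' that diagram (Robertson's isotemperature-line construction on a dense
#' locus table). `duv` is the uv distance from the locus, positive above it.
#' Sources further than `|duv| > 0.05` from the locus have no physically
#' meaningful CCT; the value is still reported but flagged.
#'
#' @param spd a `spectral_curve`.
#' @return list with `cct` (kelvin), `duv` (signed), and `warnings`
#'   (character vector; contains `"duv_out_of_range"` when `|duv| > 0.05`).
#' @examples
#' cct(planckian_spd(6500))$cct
#' @export
cct <- function(spd) {
  stopifnot(inherits(spd, "spectral_curve"))
  v <- .spd_values(spd)
  if (sum(v) <= 0) stop("SPD has no power in the visible range")
  xyz <- .tristimulus(v)
  uv <- as.numeric(.xyz_to_uv(xyz))
  tab <- .robertson_table()
  # signed distance to each isotemperature line
  d <- ((uv[2] - tab$v) - tab$slope * (uv[1] - tab$u)) / sqrt(1 + tab$slope^2)
  s <- sign(d)
  flip <- which(s[-1] * s[-length(s)] <= 0)
  if (length(flip) == 0) {
    # beyond the tabulated range: clamp to the nearest end
    i <- if (abs(d[1]) < abs(d[length(d)])) 1 else length(d)
    mired <- tab$mired[i]
  } else {
    # nearest sign change to the locus
    i <- flip[which.min(pmin(abs(d[flip]), abs(d[flip + 1])))]
    frac <- d[i] / (d[i] - d[i + 1])
    mired <- tab$mired[i] + frac * (tab$mired[i + 1] - tab$mired[i])
  }
  cct_K <- 1e6 / mired
  # locus point at the solution for the Duv sign and magnitude
  up <- stats::approx(tab$mired, tab$u, mired)$y
  vp <- stats::approx(tab$mired, tab$v, mired)$y
  duv <- sqrt((uv[1] - up)^2 + (uv[2] - vp)^2) * sign(uv[2] - vp)
  warnings <- character(0)
  if (abs(duv) > 0.05) warnings <- "duv_out_of_range"
  list(cct = cct_K, duv = duv, warnings = warnings)
}
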