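# Independent oracles used by the tests. These deliberately share no code
# with the package: scalar arithmetic written straight from the defining
# formulas, and brute-force searches where the package uses a method.

# Scalar CIEDE2000, radian arithmetic throughout.
ref_ciede2000 <- function(L1, a1, b1, L2, a2, b2) {
  C1 <- sqrt(a1 * a1 + b1 * b1)
  C2 <- sqrt(a2 * a2 + b2 * b2)
  Cm <- 0.5 * (C1 + C2)
  G <- 0.5 * (1 - sqrt(Cm^7 / (Cm^7 + 6103515625)))
  a1p <- a1 * (1 + G); a2p <- a2 * (1 + G)
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- if (C1p == 0) 0 else atan2(b1, a1p) %% (2 * pi)
  h2p <- if (C2p == 0) 0 else atan2(b2, a2p) %% (2 * pi)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  if (C1p * C2p == 0) {
    dhp <- 0
  } else {
    dhp <- h2p - h1p
    if (dhp > pi) dhp <- dhp - 2 * pi
    if (dhp < -pi) dhp <- dhp + 2 * pi
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2)
  Lm <- 0.5 * (L1 + L2); Cmp <- 0.5 * (C1p + C2p)
  if (C1p * C2p == 0) {
    hm <- h1p + h2p
  } else if (abs(h1p - h2p) <= pi) {
    hm <- 0.5 * (h1p + h2p)
  } else if (h1p + h2p < 2 * pi) {
    hm <- 0.5 * (h1p + h2p) + pi
  } else {
    hm <- 0.5 * (h1p + h2p) - pi
  }
  Tf <- 1 - 0.17 * cos(hm - pi / 6) + 0.24 * cos(2 * hm) +
    0.32 * cos(3 * hm + pi * 6 / 180) - 0.20 * cos(4 * hm - pi * 63 / 180)
  dth <- (pi / 6) * exp(-(((hm * 180 / pi) - 275) / 25)^2)
  RC <- 2 * sqrt(Cmp^7 / (Cmp^7 + 6103515625))
  SL <- 1 + 0.015 * (Lm - 50)^2 / sqrt(20 + (Lm - 50)^2)
  SC <- 1 + 0.045 * Cmp
  SH <- 1 + 0.015 * Cmp * Tf
  RT <- -sin(2 * dth) * RC
  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}

# Scalar CIEDE2000 chroma term |dC'|/SC, same scalar path as above.
ref_dc2000 <- function(L1, a1, b1, L2, a2, b2) {
  C1 <- sqrt(a1 * a1 + b1 * b1); C2 <- sqrt(a2 * a2 + b2 * b2)
  Cm <- 0.5 * (C1 + C2)
  G <- 0.5 * (1 - sqrt(Cm^7 / (Cm^7 + 6103515625)))
  C1p <- sqrt((a1 * (1 + G))^2 + b1^2)
  C2p <- sqrt((a2 * (1 + G))^2 + b2^2)
  abs(C2p - C1p) / (1 + 0.045 * 0.5 * (C1p + C2p))
}

# Brute-force CCT: 1 K grid search minimizing 1960-uv distance to the
# Planckian locus, computed directly from Planck's law and the packaged
# observer table.
brute_cct <- function(spd, Ts = seq(2000, 12000, by = 1)) {
  cmf <- chromacal::cie_cmf()
  v <- chromacal::spd_resample(spd)$value
  uv_of <- function(w) {
    X <- sum(cmf$xbar * w); Y <- sum(cmf$ybar * w); Z <- sum(cmf$zbar * w)
    den <- X + 15 * Y + 3 * Z
    c(4 * X / den, 6 * Y / den)
  }
  target <- uv_of(v)
  lam <- cmf$wavelength * 1e-9
  best_T <- NA_real_; best_d <- Inf
  for (T in Ts) {
    p <- uv_of(lam^-5 / expm1(1.4388e-2 / (lam * T)))
    d <- sqrt(sum((target - p)^2))
    if (d < best_d) { best_d <- d; best_T <- T }
  }
  best_T
}

# Independent per-patch deviation summary: direct formula evaluation, no
# package metric code.
brute_summary <- function(tab, exclude = NULL) {
  tab <- tab[!(tab$index %in% exclude), ]
  n <- nrow(tab)
  dE76 <- dC76 <- dE00 <- dC00 <- numeric(n)
  for (i in seq_len(n)) {
    m <- as.numeric(tab[i, c("L", "a", "b")])
    r <- as.numeric(tab[i, c("L_ref", "a_ref", "b_ref")])
    dE76[i] <- sqrt(sum((m - r)^2))
    dC76[i] <- abs(sqrt(m[2]^2 + m[3]^2) - sqrt(r[2]^2 + r[3]^2))
    dE00[i] <- ref_ciede2000(m[1], m[2], m[3], r[1], r[2], r[3])
    dC00[i] <- ref_dc2000(m[1], m[2], m[3], r[1], r[2], r[3])
  }
  stat <- function(x) c(avg = mean(x), min = min(x), max = max(x),
                        argmin = tab$index[which.min(x)],
                        argmax = tab$index[which.max(x)])
  rbind(dE76 = stat(dE76), dC76 = stat(dC76),
        dE00 = stat(dE00), dC00 = stat(dC00))
}

# Random in-range Lab colors for property tests.
random_lab <- function(n, Lr = c(5, 95), ab = 60) {
  cbind(stats::runif(n, Lr[1], Lr[2]),
        stats::runif(n, -ab, ab), stats::runif(n, -ab, ab))
}

load_ciede2000_pairs <- function() {
  utils::read.csv(test_path("fixtures", "ciede2000_pairs.csv"),
                  comment.char = "#")
}

# One python call against scikit-image's colorimetry; input/output via CSV.
skimage_oracle <- function(script, input_df) {
  infile <- tempfile(fileext = ".csv"); outfile <- tempfile(fileext = ".csv")
  utils::write.csv(input_df, infile, row.names = FALSE)
  full <- sprintf(script, infile, outfile)
  status <- system2("python", c("-c", shQuote(full)), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("python oracle failed: ", paste(status, collapse = "\n"))
  utils::read.csv(outfile)
}
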