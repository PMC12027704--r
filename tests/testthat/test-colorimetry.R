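test_that("chroma and the 1976 difference formulas match hand evaluation", {
  expect_equal(chroma(lab(50, 0, 0)), 0)
  expect_equal(chroma(lab(50, 3, 4)), 5)
  expect_equal(chroma(lab(10, -6, 8)), 10)

  expect_equal(delta_e_cielab(lab(50, 3, 4), lab(50, 3, 4)), 0)
  expect_equal(delta_e_cielab(lab(50, 0, 0), lab(50, 3, 4)), 5)
  expect_equal(delta_e_cielab(lab(20, 10, -10), lab(40, -10, 10)),
               sqrt(1200), tolerance = 1e-9)

  expect_equal(delta_c_cielab(lab(50, 3, 4), lab(50, 0, 0)), 5)
  expect_equal(delta_c_cielab(lab(50, 0, 0), lab(50, 3, 4)), -5)
  expect_equal(delta_l(lab(60, 0, 0), lab(50, 0, 0)), 10)
  # degenerate Euclidean case: equal a, b
  expect_equal(delta_e_cielab(lab(60, 5, -3), lab(48, 5, -3)),
               abs(delta_l(lab(60, 5, -3), lab(48, 5, -3))))
})

test_that("Lab construction validates ranges and the white point maps to (100,0,0)", {
  expect_error(lab(120, 0, 0), "L\\*")
  expect_error(lab(50, NaN, 0), "finite")
  white <- chromacal:::.d65_white
  expect_equal(as.numeric(xyz_to_lab(matrix(white, 1))), c(100, 0, 0),
               tolerance = 1e-9)
})

test_that("CIEDE2000 reproduces the 34 published verification pairs to 1e-4", {
  pairs <- load_ciede2000_pairs()
  got <- delta_e_ciede2000(as.matrix(pairs[, 1:3]), as.matrix(pairs[, 4:6]))
  expect_lt(max(abs(got - pairs$dE00)), 1e-4)
  # symmetric under argument swap for default weights
  swapped <- delta_e_ciede2000(as.matrix(pairs[, 4:6]), as.matrix(pairs[, 1:3]))
  expect_equal(got, swapped, tolerance = 1e-12)
})

test_that("CIEDE2000 identity, neutral-axis, and chroma-term properties hold", {
  set.seed(42)
  x <- random_lab(200)
  expect_equal(delta_e_ciede2000(x, x), rep(0, 200))
  expect_equal(delta_c_ciede2000(x, x), rep(0, 200))

  # neutral axis: no chroma term, total reduces to the SL-weighted lightness
  n1 <- lab(30, 0, 0); n2 <- lab(70, 0, 0)
  expect_equal(delta_c_ciede2000(n1, n2), 0)
  SL <- 1 + 0.015 * (50 - 50)^2 / sqrt(20 + 0)  # mean L = 50
  expect_equal(delta_e_ciede2000(n1, n2), 40 / SL, tolerance = 1e-12)

  # chroma term never exceeds the total difference
  y <- random_lab(200)
  expect_true(all(delta_c_ciede2000(x, y) <= delta_e_ciede2000(x, y) + 1e-12))

  # weights must be positive
  expect_error(delta_e_ciede2000(n1, n2, kC = 0), "positive")
})

test_that("the 1976 difference is a metric on random triples", {
  set.seed(7)
  a <- random_lab(1000); b <- random_lab(1000); c <- random_lab(1000)
  dab <- delta_e_cielab(a, b)
  expect_true(all(dab >= 0))
  expect_equal(dab, delta_e_cielab(b, a))
  expect_true(all(delta_e_cielab(a, a) == 0))
  expect_true(all(dab <= delta_e_cielab(a, c) + delta_e_cielab(c, b) + 1e-12))
})

test_that("sRGB decoding hits the standard anchor colors", {
  expect_equal(as.numeric(srgb_to_lab(c(255, 255, 255), bits = 8)),
               c(100, 0, 0), tolerance = 1e-6)
  expect_equal(as.numeric(srgb_to_lab(c(0, 0, 0), bits = 8)), c(0, 0, 0),
               tolerance = 1e-9)
  mid <- as.numeric(srgb_to_lab(c(118, 118, 118), bits = 8))
  expect_equal(mid[1], 49.637, tolerance = 1e-3)
  expect_equal(mid[2:3], c(0, 0), tolerance = 1e-9)
  expect_error(srgb_to_lab(c(256, 0, 0), bits = 8), "out of range")
  expect_error(srgb_to_lab(c(1.2, 0, 0)), "\\[0, 1\\]")
})

test_that("Lab <-> sRGB round trips and flags out-of-gamut colors", {
  set.seed(99)
  cand <- random_lab(20000)
  rgb <- lab_to_srgb(cand)
  ok <- !attr(rgb, "clipped")
  expect_gt(sum(ok), 10000)
  back <- srgb_to_lab(rgb[ok, ])
  expect_lt(max(abs(back - cand[ok, ])), 1e-4)

  expect_equal(as.numeric(lab_to_srgb(lab(100, 0, 0))), c(1, 1, 1),
               tolerance = 1e-9)
  neon <- lab_to_srgb(lab(70, -120, 80))
  expect_true(attr(neon, "clipped"))

  # round trip on the 24 packaged reference patch values; the classic cyan
  # (patch 18) famously sits just outside the sRGB gamut and is flagged
  ref <- reference_chart()
  enc <- lab_to_srgb(as.matrix(ref[, c("L_ref", "a_ref", "b_ref")]))
  clipped24 <- which(attr(enc, "clipped"))
  expect_equal(clipped24, 18L)
  in_gamut <- setdiff(1:24, clipped24)
  expect_lt(max(abs(srgb_to_lab(enc[in_gamut, ]) -
                    as.matrix(ref[in_gamut, c("L_ref", "a_ref", "b_ref")]))),
            1e-3)
})

test_that("conversions and CIEDE2000 agree with an independent colorimetry oracle", {
  set.seed(123)
  x <- random_lab(1000); y <- random_lab(1000)
  df <- data.frame(L1 = x[, 1], a1 = x[, 2], b1 = x[, 3],
                   L2 = y[, 1], a2 = y[, 2], b2 = y[, 3])
  out <- skimage_oracle(paste0(
    "import pandas as pd, numpy as np\n",
    "from skimage.color import deltaE_ciede2000, rgb2lab\n",
    "d = pd.read_csv('%s')\n",
    "de = deltaE_ciede2000(d[['L1','a1','b1']].values, d[['L2','a2','b2']].values)\n",
    "pd.DataFrame({'de': de}).to_csv('%s', index=False)\n"), df)
  mine <- delta_e_ciede2000(x, y)
  expect_lt(max(abs(mine - out$de)), 1e-6)

  set.seed(321)
  rgb <- matrix(runif(300), ncol = 3)
  df2 <- as.data.frame(rgb); names(df2) <- c("r", "g", "b")
  out2 <- skimage_oracle(paste0(
    "import pandas as pd, numpy as np\n",
    "from skimage.color import rgb2lab\n",
    "d = pd.read_csv('%s')\n",
    "lab = rgb2lab(d.values.reshape(-1,1,3)).reshape(-1,3)\n",
    "pd.DataFrame(lab, columns=['L','a','b']).to_csv('%s', index=False)\n"), df2)
  mine2 <- srgb_to_lab(rgb)
  # white-point constants differ in the 5th decimal between implementations
  expect_lt(max(abs(mine2 - as.matrix(out2))), 0.02)
})

test_that("Bradford adaptation is exact on the white points and invertible", {
  w1 <- chromacal:::.d50_white; w2 <- chromacal:::.d65_white
  expect_equal(as.numeric(bradford_adapt(matrix(w1, 1), w1, w2)), w2,
               tolerance = 1e-12)
  set.seed(5)
  xyz <- matrix(runif(30, 5, 95), ncol = 3)
  there <- bradford_adapt(xyz, w1, w2)
  back <- bradford_adapt(there, w2, w1)
  expect_equal(back, xyz, tolerance = 1e-9, ignore_attr = TRUE)
})
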