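test_that("SPD files round-trip, resample, and validate", {
  grid <- seq(380, 780, by = 5)
  v <- exp(-0.5 * ((grid - 560) / 80)^2)
  f <- tempfile(fileext = ".csv")
  writeLines(c("# spectrometer export", "nm,power",
               paste(grid, v, sep = ",")), f)
  spd <- load_spd(f)
  expect_equal(spd$wavelength, grid)
  expect_equal(spd$value, v, tolerance = 1e-12)

  # 1 nm file resamples to the direct linear interpolation
  fine <- seq(380, 780, by = 1)
  vf <- exp(-0.5 * ((fine - 560) / 80)^2) * (1 + 0.2 * sin(fine / 17))
  f2 <- tempfile(fileext = ".csv")
  writeLines(paste(fine, vf, sep = ","), f2)
  spd2 <- load_spd(f2)
  expect_equal(spd2$value, approx(fine, vf, grid)$y, tolerance = 1e-12)

  # descending wavelength order gives the same curve
  f3 <- tempfile(fileext = ".csv")
  writeLines(paste(rev(grid), rev(v), sep = ","), f3)
  expect_equal(load_spd(f3)$value, spd$value)

  # semicolon dialect with decimal commas
  f4 <- tempfile(fileext = ".csv")
  writeLines(gsub("\\.", ",", paste(grid, round(v, 4), sep = ";")), f4)
  expect_equal(load_spd(f4, dialect = "semicolon")$value, round(v, 4),
               tolerance = 1e-12)

  f5 <- tempfile(fileext = ".csv")
  writeLines(c("500,1", "510,-0.2"), f5)
  expect_error(load_spd(f5), "negative")
  f6 <- tempfile(fileext = ".csv")
  writeLines("500,1", f6)
  expect_error(load_spd(f6), "2")
})

test_that("normalization anchors at 555 nm and changes no downstream index", {
  spd <- dermoscope_led_spd(7080)
  n <- normalize_at(spd)
  expect_equal(n$value[n$wavelength == 555], 1)
  expect_equal(normalize_at(n)$value, n$value) # idempotent
  expect_equal(cct(n)$cct, cct(spd)$cct, tolerance = 1e-12)

  scaled <- spectral_curve(spd$wavelength, spd$value * 37.5)
  expect_equal(cct(scaled)$cct, cct(spd)$cct, tolerance = 1e-12)
  expect_equal(cri(scaled)$ra, cri(spd)$ra, tolerance = 1e-9)
  expect_equal(tlci(scaled)$qa, tlci(spd)$qa, tolerance = 1e-9)

  dark <- spectral_curve(c(600, 700, 780), c(0, 1, 1))
  expect_error(normalize_at(dark, 450), "support")
  expect_error(normalize_at(spd_resample(dark), 400), "zero power")
})

test_that("CCT recovers Planckian temperatures and flags far-off-locus sources", {
  got <- cct(planckian_spd(6500))
  expect_equal(got$cct, 6500, tolerance = 10 / 6500)
  expect_lt(abs(got$duv), 1e-5)
  expect_equal(cct(planckian_spd(3000))$cct, 3000, tolerance = 5 / 3000)

  ee <- spectral_curve(seq(380, 780, 5), rep(1, 81), "equal energy")
  oracle <- brute_cct(ee, Ts = seq(5000, 6000, by = 1))
  expect_equal(cct(ee)$cct, oracle, tolerance = 2 / oracle)
  expect_equal(cct(ee)$cct, 5455, tolerance = 5 / 5455)

  # daylight sits slightly above the Planckian locus
  expect_gt(cct(daylight_spd(6504))$duv, 0)

  green <- led_spd(list(c(530, 40, 1)))
  expect_true("duv_out_of_range" %in% cct(green)$warnings)
  expect_length(cct(planckian_spd(5000))$warnings, 0)
})

test_that("CRI scores the reference illuminants at 100 and degrades narrow bands", {
  r <- cri(planckian_spd(3000))
  expect_equal(r$ra, 100, tolerance = 0.1 / 100)
  expect_true(all(abs(r$ri - 100) < 0.1))
  expect_equal(cri(daylight_spd(6500))$ra, 100, tolerance = 0.1 / 100)

  tri <- led_spd(list(c(450, 20, 1), c(550, 20, 1), c(650, 20, 1)))
  ra_tri <- cri(tri)$ra
  expect_lt(ra_tri, 90)
  expect_equal(ra_tri, 77.2909, tolerance = 1e-4) # frozen regression anchor

  # Ra decreases monotonically as the bands narrow
  ras <- vapply(c(80, 60, 40, 20, 10), function(fw)
    cri(led_spd(list(c(450, fw, 1), c(550, fw, 1), c(650, fw, 1))))$ra,
    numeric(1))
  expect_true(all(diff(ras) < 0))
})

test_that("TLCI is exactly 100 when the test source equals its reference", {
  tl <- tlci(daylight_spd(5600))
  expect_equal(tl$qa, 100, tolerance = 0.01 / 100)
  expect_lt(tl$mean_de00, 0.01)
  expect_equal(tlci(planckian_spd(3000))$qa, 100, tolerance = 0.01 / 100)

  # identity inside the blend band, via the internal reference constructor
  mid <- spectral_curve(seq(380, 780, 5),
                        chromacal:::.tlci_reference_values(4500))
  expect_equal(tlci(mid)$qa, 100, tolerance = 0.1 / 100)

  tri <- led_spd(list(c(450, 20, 1), c(550, 20, 1), c(650, 20, 1)))
  qa_tri <- tlci(tri)$qa
  expect_equal(qa_tri, 36.9522, tolerance = 1e-3) # frozen regression anchor
  expect_lt(qa_tri, cri(tri)$ra) # camera chain is harsher than the CRI here
})

test_that("light-quality reports bundle the indices and serialize to JSON", {
  rep3000 <- light_quality_report(planckian_spd(3000))
  expect_s3_class(rep3000, "light_quality_report")
  expect_equal(rep3000$cct_K, 3000, tolerance = 5 / 3000)
  expect_equal(rep3000$ra, 100, tolerance = 0.1 / 100)
  expect_equal(rep3000$tlci, 100, tolerance = 0.1 / 100)
  expect_length(rep3000$ri, 14)
  expect_length(rep3000$warnings, 0)

  led <- dermoscope_led_spd(7080)
  repled <- light_quality_report(led)
  expect_equal(repled$cct_K, 7080, tolerance = 1 / 7080)
  expect_true(repled$ra < 100 && repled$tlci < 100)
  expect_length(repled$warnings, 0)

  f <- tempfile(fileext = ".json")
  write_light_report(repled, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$cct_K, repled$cct_K)
  expect_length(parsed$ri, 14)
})

test_that("spectral generators validate their temperature ranges", {
  expect_error(planckian_spd(1500), "2000")
  expect_error(daylight_spd(3000), "4000")
  expect_error(led_spd(list(c(900, 20, 1))), "380-780")
  expect_error(led_spd(list()), "at least one")
  two <- led_spd(list(c(460, 25, 1), c(550, 80, 0.9)))
  expect_equal(max(two$value), 1)
  # two-lobed: a local minimum between the blue pump and the phosphor band
  i460 <- which(two$wavelength == 460); i550 <- which(two$wavelength == 550)
  expect_lt(min(two$value[i460:i550]), two$value[i460])
  expect_lt(min(two$value[i460:i550]), two$value[i550])
})
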