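test_that("the packaged reference chart is complete and neutral where expected", {
  ref <- reference_chart()
  expect_equal(nrow(ref), 24)
  expect_equal(ref$index, 1:24)
  expect_false(anyDuplicated(ref$name) > 0)
  expect_equal(ref$name[1], "dark skin")
  # row 4 is the neutral ramp: near-zero chroma after adaptation to D65
  neutrals <- ref[19:24, ]
  expect_true(all(abs(neutrals$a_ref) < 2.5 & abs(neutrals$b_ref) < 2.5))
  expect_true(all(diff(neutrals$L_ref) < 0)) # white 9.5 down to black 2
})

test_that("detection without a hint recovers the rendered geometry", {
  rc <- render_chart(distortion = camera_distortion(noise_sigma = 1, seed = 3))
  regions <- detect_chart(rc$image)
  expect_length(regions, 24)
  for (i in 1:24) {
    got <- colMeans(regions[[i]]$polygon)
    truth <- colMeans(rc$regions[[i]]$polygon)
    expect_lt(max(abs(got - truth)), 1)
  }
  # degenerate input fails explicitly
  blank <- array(0.5, c(60, 80, 3))
  expect_error(detect_chart(blank), "chart not found")
})

test_that("detection with a corner hint equals the warped canonical grid", {
  corners <- matrix(c(12, 9, 240, 21, 250, 170, 7, 158), ncol = 2, byrow = TRUE)
  rc <- render_chart(corners = corners, patch_px = 32, border_px = 8)
  regions <- detect_chart(rc$image, hint = corners, border_frac = 8 / 32)
  for (i in 1:24) {
    expect_equal(regions[[i]]$polygon, rc$regions[[i]]$polygon,
                 tolerance = 1e-9)
  }
  expect_error(detect_chart(rc$image, hint = corners * 100), "bounds")
  # measurement through the warp still lands on the right colors
  tab <- measure_patches(rc$image, regions)
  ev <- evaluate_table(tab, reference_chart())
  expect_lt(ev$summary$avg[ev$summary$metric == "dE00"], 0.5)
})

test_that("patch measurement is exact on constant regions and robust to outliers", {
  img <- array(0, c(120, 120, 3))
  img[, , 1] <- 0.6; img[, , 2] <- 0.4; img[, , 3] <- 0.2
  reg <- patch_region(1, matrix(c(10, 10, 110, 10, 110, 110, 10, 110),
                                ncol = 2, byrow = TRUE))
  tab <- measure_patches(img, list(reg))
  expect_equal(as.numeric(tab[1, c("R", "G", "B")]), c(0.6, 0.4, 0.2))

  # Gaussian noise: the sampling error follows the 3 sigma / sqrt(n) bound
  set.seed(10)
  n_img <- img + array(rnorm(length(img), sd = 2 / 255), dim(img))
  tab_n <- measure_patches(n_img, list(reg), trim = 0)
  n_px <- sum(chromacal:::.in_convex_poly(
    cbind(rep(1:120, each = 120) - 0.5, rep(1:120, 120) - 0.5),
    chromacal:::.shrink_poly(reg$polygon, 0.5)))
  expect_gt(n_px, 2000)
  expect_lt(max(abs(as.numeric(tab_n[1, c("R", "G", "B")]) - c(0.6, 0.4, 0.2))),
            3 * (2 / 255) / sqrt(n_px))

  # 10% salt-and-pepper: the trimmed mean shrugs it off
  set.seed(11)
  sp <- img
  flat <- matrix(sp, ncol = 3)
  hit <- sample(nrow(flat), round(0.1 * nrow(flat)))
  flat[hit, ] <- rep(c(0, 1), length.out = length(hit))
  sp <- array(flat, dim(img))
  tab_sp <- measure_patches(sp, list(reg))
  expect_lt(max(abs(as.numeric(tab_sp[1, c("R", "G", "B")]) - c(0.6, 0.4, 0.2))),
            1 / 255)

  off <- patch_region(2, matrix(c(-50, -50, -40, -50, -40, -40, -50, -40),
                                ncol = 2, byrow = TRUE))
  expect_error(measure_patches(img, list(off)), "patch 2")
})

test_that("single-patch acquisition matches full-chart measurement", {
  d <- camera_distortion(gains = c(1.15, 1, 0.9))
  rc <- render_chart(distortion = d)
  full <- measure_patches(rc$image, rc$regions)
  frames <- render_single_patches(distortion = d)
  single <- assemble_single_patch_table(frames)
  expect_equal(single$index, 1:24)
  expect_lt(max(abs(as.matrix(full[, c("R", "G", "B")]) -
                    as.matrix(single[, c("R", "G", "B")]))), 1 / 255)

  one <- assemble_single_patch_table(frames[5])
  expect_equal(nrow(one), 1)
  expect_equal(one$index, 5)
  expect_error(assemble_single_patch_table(c(frames[5], frames[5])),
               "duplicate")
  bad <- list(list(index = 30, image = frames[[1]]$image))
  expect_error(assemble_single_patch_table(bad), "range")
})

test_that("evaluation fills metrics row-wise and summarizes correctly", {
  ref <- reference_chart()
  # measured == reference: everything zero
  perfect <- data.frame(index = 1:24, name = NA_character_,
                        R = NA_real_, G = NA_real_, B = NA_real_,
                        L = ref$L_ref, a = ref$a_ref, b = ref$b_ref)
  class(perfect) <- c("color_table", "data.frame")
  ev <- evaluate_table(perfect, ref)
  expect_true(all(abs(c(ev$summary$avg, ev$summary$min, ev$summary$max)) < 1e-12))
  expect_equal(ev$table$name, ref$name)

  # a pure lightness shift of 5 (down: all 24 L* values stay in range)
  shifted <- perfect
  shifted$L <- shifted$L - 5
  ev2 <- evaluate_table(shifted, ref)
  s <- ev2$summary
  expect_equal(s$avg[s$metric == "dE76"], 5, tolerance = 1e-12)
  expect_equal(s$min[s$metric == "dE76"], 5, tolerance = 1e-12)
  expect_equal(s$max[s$metric == "dE76"], 5, tolerance = 1e-12)
  expect_equal(s$avg[s$metric == "dC76"], 0, tolerance = 1e-12)
  expect_equal(ev2$table$dL, rep(-5, 24), tolerance = 1e-12)

  # exclusion can only shrink the [min, max] interval
  d <- camera_distortion(gains = c(1.2, 1, 0.8))
  rc <- render_chart(distortion = d)
  tab <- measure_patches(rc$image, rc$regions)
  all_ev <- evaluate_table(tab, ref)
  sub_ev <- evaluate_table(tab, ref, exclude = c(1, 10, 13))
  expect_equal(nrow(sub_ev$table), 24) # table keeps all rows
  for (m in c("dE76", "dC76", "dE00", "dC00")) {
    expect_gte(sub_ev$summary$min[sub_ev$summary$metric == m],
               all_ev$summary$min[all_ev$summary$metric == m])
    expect_lte(sub_ev$summary$max[sub_ev$summary$metric == m],
               all_ev$summary$max[all_ev$summary$metric == m])
  }
  expect_error(evaluate_table(tab, ref, exclude = 1:24), "no patches")

  stray <- perfect; stray$index[1] <- 99L
  expect_error(evaluate_table(stray, ref), "not present")
})

test_that("deviation summaries equal the independent brute-force recomputation", {
  d <- camera_distortion(gains = c(1.2, 1, 0.8), noise_sigma = 1.5, seed = 21)
  rc <- render_chart(distortion = d)
  ev <- evaluate_table(measure_patches(rc$image, rc$regions), reference_chart())
  oracle <- brute_summary(ev$table)
  got <- as.matrix(ev$summary[, c("avg", "min", "max", "argmin", "argmax")])
  rownames(got) <- ev$summary$metric
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("color tables round-trip through CSV and reject malformed files", {
  d <- camera_distortion(gains = c(0.9, 1, 1.1))
  rc <- render_chart(distortion = d)
  ev <- evaluate_table(measure_patches(rc$image, rc$regions), reference_chart())
  f <- tempfile(fileext = ".csv")
  write_color_table(ev$table, f)
  back <- read_color_table(f)
  expect_equal(back$index, ev$table$index)
  expect_equal(back$name, ev$table$name)
  num <- setdiff(chromacal:::.color_table_cols, "name")
  expect_equal(as.matrix(back[, num]), as.matrix(ev$table[, num]),
               tolerance = 1e-12)

  # a partial 23-row table is valid
  part <- ev$table[1:23, ]
  class(part) <- c("color_table", "data.frame")
  write_color_table(part, f)
  expect_equal(nrow(read_color_table(f)), 23)

  # corrupt one numeric cell: parse error names column and line
  lines <- readLines(f)
  lines[5] <- sub("^(\"?[0-9]+\"?,\"[^\"]*\",)[-0-9.e]+", "\\1oops", lines[5])
  writeLines(lines, f)
  expect_error(read_color_table(f), "non-numeric value.*line 4")

  writeLines(c("a,b", "1,2"), f)
  expect_error(read_color_table(f), "header mismatch")
})

test_that("summary JSON carries per-metric stats and extremes", {
  d <- camera_distortion(gains = c(1.3, 1, 0.75))
  rc <- render_chart(distortion = d)
  ev <- evaluate_table(measure_patches(rc$image, rc$regions), reference_chart())
  f <- tempfile(fileext = ".json")
  write_summary_json(ev$summary, f)
  parsed <- jsonlite::fromJSON(f)
  expect_setequal(names(parsed), c("dE76", "dC76", "dE00", "dC00"))
  expect_equal(parsed$dE00$avg,
               ev$summary$avg[ev$summary$metric == "dE00"])
  expect_true(parsed$dE76$argmax %in% 1:24)
})
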