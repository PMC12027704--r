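# ColorChecker chart handling: reference values, patch detection and
# measurement, deviation metrics and summaries.

.patch_rows <- 4L
.patch_cols <- 6L

#' Reference chart values
#'
#' The packaged 24-patch reference set uses the classic (pre-2015) chart
#' values, stored in CIELAB under their native D50 illuminant and adapted to
#' D65 with the Bradford transform (camera sRGB output is interpreted under
#' D65 throughout the package). A user CSV with columns
#' `index,name,L,a,b` may be supplied instead.
#'
#' @param csv optional path to a replacement reference CSV (Lab under D50).
#' @param adapt_to `"D65"` (default) or `"none"` to keep native values.
#' @return object of class `reference_chart`: a data.frame with columns
#'   `index`, `name`, `L_ref`, `a_ref`, `b_ref`.
#' @export
reference_chart <- function(csv = NULL, adapt_to = c("D65", "none")) {
  adapt_to <- match.arg(adapt_to)
  path <- if (is.null(csv)) .extdata("colorchecker_classic_lab_d50.csv") else csv
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("index", "name", "L", "a", "b") %in% names(d)))
  if (nrow(d) != 24 || anyDuplicated(d$name) || anyDuplicated(d$index))
    stop("a reference chart needs 24 uniquely named patches")
  d <- d[order(d$index), ]
  labm <- as.matrix(d[, c("L", "a", "b")])
  if (adapt_to == "D65") {
    xyz <- lab_to_xyz(labm, white = .d50_white)
    labm <- xyz_to_lab(bradford_adapt(xyz, .d50_white, .d65_white))
  }
  out <- data.frame(index = d$index, name = d$name,
                    L_ref = labm[, 1], a_ref = labm[, 2], b_ref = labm[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_chart", "data.frame")
  out
}

#' Patch regions
#'
#' A patch region is a convex quadrilateral in continuous image coordinates
#' (origin top-left, x rightward, y downward, pixel centers at half-integer
#' offsets), stored clockwise, tagged with the 1-24 patch index.
#'
#' @param index patch index in 1..24.
#' @param polygon 4 x 2 matrix of (x, y) corners, clockwise.
#' @return object of class `patch_region`.
#' @export
patch_region <- function(index, polygon) {
  polygon <- matrix(as.numeric(polygon), ncol = 2)
  if (nrow(polygon) != 4) stop("patch polygon must have 4 corners")
  if (!index %in% 1:24) stop("patch index must be in 1..24")
  structure(list(index = as.integer(index), polygon = polygon),
            class = "patch_region")
}

# Canonical patch polygons in unit chart coordinates for a 4 x 6 layout
# whose inter-patch border width is `border_frac` of the patch side.
.canonical_polys <- function(border_frac = 0.25) {
  f <- border_frac
  Wu <- .patch_cols + (.patch_cols + 1) * f
  Hu <- .patch_rows + (.patch_rows + 1) * f
  polys <- vector("list", 24)
  for (r in 1:.patch_rows) for (c in 1:.patch_cols) {
    idx <- (r - 1) * .patch_cols + c
    x0 <- (f + (c - 1) * (1 + f)) / Wu; x1 <- x0 + 1 / Wu
    y0 <- (f + (r - 1) * (1 + f)) / Hu; y1 <- y0 + 1 / Hu
    polys[[idx]] <- matrix(c(x0, y0, x1, y0, x1, y1, x0, y1),
                           ncol = 2, byrow = TRUE)
  }
  polys
}

# Projective map from the unit square to four image corners (TL, TR, BR, BL),
# solved by direct linear transformation with h33 = 1.
.homography_from_corners <- function(corners) {
  src <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    X <- src[i, 1]; Y <- src[i, 2]; x <- corners[i, 1]; y <- corners[i, 2]
    A[2 * i - 1, ] <- c(X, Y, 1, 0, 0, 0, -x * X, -x * Y)
    A[2 * i, ]     <- c(0, 0, 0, X, Y, 1, -y * X, -y * Y)
    b[2 * i - 1] <- x; b[2 * i] <- y
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

.apply_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2] / p[, 3]
}

# Run-based connected-component labeling of a logical matrix (4-neighbor),
# with union-find over row runs.
.label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (i in seq_len(H)) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      above <- if (i > 1) unique(lab[i - 1, s:e]) else integer(0)
      above <- above[above > 0L]
      if (length(above) == 0) {
        parent[length(parent) + 1L] <- length(parent) + 1L
        id <- length(parent)
      } else {
        id <- find(above[1])
        for (a in above[-1]) unite(id, a)
      }
      lab[i, s:e] <- id
    }
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    remap <- match(roots, sort(unique(roots)))
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Locate the 24 chart patches in an image
#'
#' With corner `hint` given (4 x 2 matrix: the chart's outer corners in
#' order top-left, top-right, bottom-right, bottom-left), patch regions are
#' the canonical 4 x 6 grid mapped through the homography those corners
#' define -- the deterministic reference behavior. Without a hint, automatic
#' detection segments the bright patches from the dark chart grid: a
#' luminance threshold is searched over, connected components are labeled,
#' and a candidate segmentation is accepted only if it yields exactly 24
#' compact, similarly sized components that organize into 4 rows of 6.
#' Anything else fails explicitly; a partial result is never returned.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param sensitivity in (0, 1\]: scales how exhaustively thresholds are
#'   searched (more candidate thresholds at higher values).
#' @param hint optional 4 x 2 corner matrix (see above).
#' @param border_frac inter-patch border width as a fraction of the patch
#'   side, used by the hint path's canonical grid.
#' @return list of 24 `patch_region`s in chart order.
#' @export
detect_chart <- function(image, sensitivity = 0.7, hint = NULL,
                         border_frac = 0.25) {
  image <- .check_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (!is.null(hint)) {
    hint <- matrix(as.numeric(hint), ncol = 2)
    if (nrow(hint) != 4) stop("hint must be a 4 x 2 corner matrix")
    if (any(hint[, 1] < 0 | hint[, 1] > W | hint[, 2] < 0 | hint[, 2] > H))
      stop("hint corners outside image bounds")
    Hm <- .homography_from_corners(hint)
    polys <- .canonical_polys(border_frac)
    return(lapply(1:24, function(i)
      patch_region(i, .apply_homography(Hm, polys[[i]]))))
  }
  if (sensitivity <= 0 || sensitivity > 1) stop("sensitivity must be in (0, 1]")
  lum <- srgb_decode(image[, , 1]) * 0.2126 + srgb_decode(image[, , 2]) * 0.7152 +
    srgb_decode(image[, , 3]) * 0.0722
  probs <- seq(0.02, 0.75, length.out = round(8 + 32 * sensitivity))
  cand <- unique(stats::quantile(lum, probs, names = FALSE))
  for (t in cand) {
    regions <- .try_threshold(lum, t)
    if (!is.null(regions)) return(regions)
  }
  stop("chart not found: no luminance threshold yields a 4 x 6 patch grid")
}

# Attempt one threshold; NULL unless it produces a clean 24-patch grid.
.try_threshold <- function(lum, t) {
  lab <- .label_components(lum > t)
  n <- max(lab)
  if (n < 24) return(NULL)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  big <- order(sizes, decreasing = TRUE)[1:min(n, 24)]
  keep <- which(sizes >= 0.5 * stats::median(sizes[big]) & sizes >= 9)
  if (length(keep) != 24) return(NULL)
  # a clean separation: thresholds inside the background noise band leave
  # many stray foreground pixels outside the 24 patches
  if (sum(sizes[keep]) / sum(sizes) < 0.98) return(NULL)
  stats <- lapply(keep, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    # percentile bounds: a few stray noise pixels fused to a patch must not
    # move its box
    rmin <- stats::quantile(w[, 1], 0.01, type = 1, names = FALSE)
    rmax <- stats::quantile(w[, 1], 0.99, type = 1, names = FALSE)
    cmin <- stats::quantile(w[, 2], 0.01, type = 1, names = FALSE)
    cmax <- stats::quantile(w[, 2], 0.99, type = 1, names = FALSE)
    bh <- rmax - rmin + 1; bw <- cmax - cmin + 1
    list(size = nrow(w), bh = bh, bw = bw,
         fill = nrow(w) / (bh * bw),
         cx = (cmin - 1 + cmax) / 2, cy = (rmin - 1 + rmax) / 2,
         x0 = cmin - 1, x1 = cmax, y0 = rmin - 1, y1 = rmax)
  })
  if (any(vapply(stats, function(s) s$fill < 0.7 ||
                 s$bw / s$bh > 2 || s$bh / s$bw > 2, TRUE))) return(NULL)
  cy <- vapply(stats, `[[`, numeric(1), "cy")
  cx <- vapply(stats, `[[`, numeric(1), "cx")
  # split into 4 rows at the 3 largest vertical gaps
  o <- order(cy)
  gaps <- diff(cy[o])
  cuts <- sort(order(gaps, decreasing = TRUE)[1:3])
  row_id <- integer(24)
  row_id[o] <- rep(1:4, times = diff(c(0, cuts, 24)))
  if (!all(tabulate(row_id, 4) == 6)) return(NULL)
  regions <- vector("list", 24)
  for (r in 1:4) {
    members <- which(row_id == r)
    members <- members[order(cx[members])]
    for (c in 1:6) {
      s <- stats[[members[c]]]
      idx <- (r - 1) * 6 + c
      regions[[idx]] <- patch_region(idx, matrix(
        c(s$x0, s$y0, s$x1, s$y0, s$x1, s$y1, s$x0, s$y1),
        ncol = 2, byrow = TRUE))
    }
  }
  regions
}

# Scale a polygon about its centroid.
.shrink_poly <- function(poly, factor) {
  ctr <- colMeans(poly)
  sweep(sweep(poly, 2, ctr, "-") * factor, 2, ctr, "+")
}

# Logical: which points (n x 2) lie inside a convex polygon.
.in_convex_poly <- function(pts, poly) {
  inside <- rep(TRUE, nrow(pts)); sgn <- NULL
  for (k in seq_len(nrow(poly))) {
    p1 <- poly[k, ]; p2 <- poly[if (k == nrow(poly)) 1 else k + 1, ]
    cr <- (p2[1] - p1[1]) * (pts[, 2] - p1[2]) - (p2[2] - p1[2]) * (pts[, 1] - p1[1])
    if (is.null(sgn)) sgn <- sign(sum(cr))
    inside <- inside & (cr * sgn >= 0)
  }
  inside
}

# Trimmed per-channel mean of the pixels whose centers fall in a polygon.
.poly_mean <- function(image, poly, trim) {
  H <- dim(image)[1]; W <- dim(image)[2]
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  c0 <- max(1, floor(xr[1] + 0.5)); c1 <- min(W, ceiling(xr[2] + 0.5))
  r0 <- max(1, floor(yr[1] + 0.5)); r1 <- min(H, ceiling(yr[2] + 0.5))
  if (c1 < c0 || r1 < r0) return(NULL)
  cols <- c0:c1; rows <- r0:r1
  grid <- expand.grid(y = rows, x = cols)
  pts <- cbind(grid$x - 0.5, grid$y - 0.5)
  inside <- .in_convex_poly(pts, poly)
  if (!any(inside)) return(NULL)
  sel <- grid[inside, ]
  vapply(1:3, function(ch)
    mean(image[cbind(sel$y, sel$x, ch)], trim = trim), numeric(1))
}

#' Measure patch colors
#'
#' For each region, samples the central area (the polygon shrunk about its
#' centroid, keeping `1 - 2 * margin` of each side) and takes a two-sided
#' trimmed mean per channel, robust to specular outliers and dust. Measured
#' CIELAB values come from [srgb_to_lab()].
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param regions list of `patch_region`s.
#' @param margin fraction trimmed from each side of the patch; default 0.25
#'   (the central half of each dimension is sampled).
#' @param trim two-sided trim fraction of the pixel mean; default 0.1.
#' @return a `color_table` data.frame with columns `index`, `name`
#'   (`NA` until evaluated), measured `R`, `G`, `B` in \[0, 1\] and `L`,
#'   `a`, `b`.
#' @export
measure_patches <- function(image, regions, margin = 0.25, trim = 0.1) {
  image <- .check_image(image)
  rows <- lapply(regions, function(reg) {
    stopifnot(inherits(reg, "patch_region"))
    poly <- .shrink_poly(reg$polygon, 1 - 2 * margin)
    rgb <- .poly_mean(image, poly, trim)
    if (is.null(rgb))
      stop("empty sampling region for patch ", reg$index)
    labv <- srgb_to_lab(rgb)
    data.frame(index = reg$index, name = NA_character_,
               R = rgb[1], G = rgb[2], B = rgb[3],
               L = labv[1], a = labv[2], b = labv[3])
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$index)) stop("duplicate patch index in regions")
  class(tab) <- c("color_table", "data.frame")
  tab
}

#' Assemble a color table from single-patch captures
#'
#' Dermoscope optics restrict the field of view to a single patch, so chart
#' patches are photographed one frame each. Each frame's central region
#' (a centered rectangle covering `central_frac` of each dimension) is
#' measured with the same trimmed mean as [measure_patches()], and the rows
#' are merged into one `color_table`.
#'
#' @param captures list of `list(index =, image =)` entries; indices must be
#'   unique and in 1..24.
#' @param central_frac fraction of each image dimension sampled; default 0.5.
#' @param trim two-sided trim fraction; default 0.1.
#' @return a `color_table` (possibly partial).
#' @export
assemble_single_patch_table <- function(captures, central_frac = 0.5,
                                        trim = 0.1) {
  idx <- vapply(captures, function(cp) as.integer(cp$index), integer(1))
  if (anyDuplicated(idx)) stop("duplicate patch index ", idx[duplicated(idx)][1])
  if (any(!idx %in% 1:24)) stop("patch index out of range 1..24")
  rows <- lapply(captures, function(cp) {
    img <- .check_image(cp$image)
    H <- dim(img)[1]; W <- dim(img)[2]
    poly <- matrix(c(0, 0, W, 0, W, H, 0, H), ncol = 2, byrow = TRUE)
    poly <- .shrink_poly(poly, central_frac)
    rgb <- .poly_mean(img, poly, trim)
    if (is.null(rgb)) stop("empty sampling region for patch ", cp$index)
    labv <- srgb_to_lab(rgb)
    data.frame(index = as.integer(cp$index), name = NA_character_,
               R = rgb[1], G = rgb[2], B = rgb[3],
               L = labv[1], a = labv[2], b = labv[3])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$index), ]
  rownames(tab) <- NULL
  class(tab) <- c("color_table", "data.frame")
  tab
}

#' Evaluate a color table against reference values
#'
#' Joins measured patches to the reference chart, fills the per-patch
#' deviation metrics (CIELAB `dE76`, signed `dC76`, `dL`; CIEDE2000 `dE00`
#' and its chroma term `dC00`), and summarizes each metric over the
#' non-excluded patches. Summaries of the signed chroma difference use its
#' magnitude. The `exclude` option drops patches whose saturated colors are
#' uncommon in clinical imagery.
#'
#' @param table a `color_table` from [measure_patches()] or
#'   [assemble_single_patch_table()].
#' @param reference a `reference_chart`.
#' @param exclude optional integer vector of patch indices to drop from the
#'   summary (they remain in the returned table).
#' @return list with `table` (deviation columns filled) and `summary` (a
#'   `deviation_summary`: one row per metric with avg/min/max and the patch
#'   index attaining each extreme).
#' @export
evaluate_table <- function(table, reference, exclude = NULL) {
  stopifnot(inherits(table, "color_table"), inherits(reference, "reference_chart"))
  if (any(!table$index %in% reference$index))
    stop("color table contains indices not present in the reference chart")
  ref <- reference[match(table$index, reference$index), ]
  meas <- as.matrix(table[, c("L", "a", "b")])
  refm <- as.matrix(ref[, c("L_ref", "a_ref", "b_ref")])
  table$name <- ref$name
  table$L_ref <- refm[, 1]; table$a_ref <- refm[, 2]; table$b_ref <- refm[, 3]
  table$dE76 <- delta_e_cielab(meas, refm)
  table$dC76 <- delta_c_cielab(meas, refm)
  table$dL <- delta_l(meas, refm)
  table$dE00 <- delta_e_ciede2000(meas, refm)
  table$dC00 <- delta_c_ciede2000(meas, refm)
  keep <- !(table$index %in% exclude)
  if (!any(keep)) stop("no patches left after exclusion")
  sub <- table[keep, ]
  metr <- list(dE76 = sub$dE76, dC76 = abs(sub$dC76),
               dE00 = sub$dE00, dC00 = sub$dC00)
  summary <- do.call(rbind, lapply(names(metr), function(m) {
    x <- metr[[m]]
    data.frame(metric = m, avg = mean(x), min = min(x), max = max(x),
               argmin = sub$index[which.min(x)],
               argmax = sub$index[which.max(x)])
  }))
  class(summary) <- c("deviation_summary", "data.frame")
  class(table) <- c("color_table", "data.frame")
  list(table = table, summary = summary)
}

#' @export
print.deviation_summary <- function(x, ...) {
  cat("Color deviation summary (avg / min / max, extremes by patch index)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-5s %6.1f / %5.1f (#%d) / %5.1f (#%d)\n",
                x$metric[i], x$avg[i], x$min[i], x$argmin[i],
                x$max[i], x$argmax[i]))
  }
  invisible(x)
}

.color_table_cols <- c("index", "name", "R", "G", "B", "L", "a", "b",
                       "L_ref", "a_ref", "b_ref",
                       "dE76", "dC76", "dL", "dE00", "dC00")

#' Color table CSV round trip
#'
#' Writes/reads a `color_table` with the fixed column header
#' `index,name,R,G,B,L,a,b,L_ref,a_ref,b_ref,dE76,dC76,dL,dE00,dC00`
#' (unevaluated columns are empty). The round trip is lossless well beyond
#' 6 significant digits.
#'
#' @param table a `color_table`.
#' @param path CSV file path.
#' @return `write_color_table()` returns `path` invisibly;
#'   `read_color_table()` returns a `color_table`.
#' @export
write_color_table <- function(table, path) {
  stopifnot(inherits(table, "color_table"))
  out <- table
  for (cl in setdiff(.color_table_cols, names(out))) out[[cl]] <- NA_real_
  out <- out[, .color_table_cols]
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_color_table
#' @export
read_color_table <- function(path) {
  if (!file.exists(path)) stop("color table file not found: ", path)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("malformed color table CSV: ",
                                         conditionMessage(e)))
  if (!identical(names(d), .color_table_cols))
    stop("color table header mismatch; expected ",
         paste(.color_table_cols, collapse = ","))
  num_cols <- setdiff(.color_table_cols, "name")
  for (cl in num_cols) {
    raw <- d[[cl]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(trimws(as.character(raw))) & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at data line %d of %s",
                   cl, bad[1], path))
    d[[cl]] <- v
  }
  if (anyDuplicated(d$index)) stop("duplicate patch index in ", path)
  d$index <- as.integer(d$index)
  class(d) <- c("color_table", "data.frame")
  d
}

#' Serialize a deviation summary to JSON
#'
#' One object per metric with `avg`, `min`, `max`, `argmin`, `argmax`.
#'
#' @param summary a `deviation_summary`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @export
write_summary_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "deviation_summary"))
  obj <- stats::setNames(lapply(seq_len(nrow(summary)), function(i)
    list(avg = summary$avg[i], min = summary$min[i], max = summary$max[i],
         argmin = summary$argmin[i], argmax = summary$argmax[i])),
    summary$metric)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
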