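# Raster image I/O. Images are H x W x 3 numeric arrays with encoded sRGB
# values in [0, 1]; pixel (i, j) has its center at continuous coordinates
# (x = j - 0.5, y = i - 0.5), origin at the top-left corner, x rightward,
# y downward.

#' Read an RGB image
#'
#' Decodes PNG and TIFF (8- or 16-bit) via the `png` and `tiff` packages;
#' JPEG is decoded through `EBImage` when that package is available. Gray
#' images are expanded to three channels and any alpha channel is dropped.
#'
#' @param path image file; format chosen by extension.
#' @return H x W x 3 array of values in \[0, 1\], with attribute
#'   `bit_depth` (8 or 16) where the decoder reports it.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG decoding requires the EBImage package")
      e <- EBImage::readImage(path)
      aperm(EBImage::imageData(e), if (length(dim(e)) == 3) c(2, 1, 3) else c(2, 1))
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] < 3) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  img
}

#' Write an RGB image as PNG
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

.check_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("expected an H x W x 3 RGB array")
  img
}

# Flatten an image to an n x 3 matrix of pixels.
.pixels <- function(img) {
  d <- dim(img)
  matrix(img, d[1] * d[2], 3)
}
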