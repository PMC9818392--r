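# Raster I/O. PNG goes through the png package directly; JPEG and TIFF are
# decoded by EBImage. Arrays are (h, w, c) in [0, 1] throughout the package
# (EBImage stores width-major, so its data are transposed on the way in/out).

read_raster <- function(path) {
  assert_that(file.exists(path), paste0("file does not exist: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else {
    img <- EBImage::readImage(path)
    x <- EBImage::imageData(img)
    x <- if (length(dim(x)) == 2L) t(x) else aperm(x, c(2, 1, 3))
  }
  x
}

#' Read an RGB image
#'
#' @param path PNG, JPEG or TIFF file (8-bit).
#' @return `(h, w, 3)` array with values in `[0, 1]`; grayscale inputs are
#'   replicated across channels, alpha channels are dropped.
#' @export
load_image <- function(path) {
  x <- read_raster(path)
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x, 3L), dim = c(dim(x)[1:2], 3L))
  pmin(pmax(x, 0), 1)
}

#' Read a binary mask
#'
#' 8-bit mask images are binarized with the pixel > 127 rule; multi-channel
#' mask files are reduced to their first channel first.
#'
#' @param path PNG, JPEG or TIFF file.
#' @return binary `(h, w)` matrix with values in {0, 1}.
#' @export
load_mask <- function(path) {
  x <- read_raster(path)
  if (!is.matrix(x)) x <- x[, , 1]
  out <- (x > 127 / 255) * 1
  out
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask binary `(h, w)` matrix.
#' @param path output file (PNG).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_that(is_binary(mask), "mask must be binary")
  png::writePNG(mask, path)  # {0,1} doubles -> 8-bit {0,255}
  invisible(path)
}

write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
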