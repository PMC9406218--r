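# Image I/O and resampling glue. 8-bit RGB images and binary masks go
# through the png package; 16-bit instance maps through EBImage; bilinear /
# nearest-neighbour resampling and Gaussian blur through EBImage.

# resize dim1 x dim2 (rows x cols); EBImage's first dimension maps to our
# rows, so targets are passed in that order
resize_bilinear <- function(x, h, w) {
  as.array(EBImage::resize(x, w = h, h = w, filter = "bilinear"))
}

resize_nearest <- function(x, h, w) {
  out <- EBImage::resize(x, w = h, h = w, filter = "none")
  as.array(out)
}

gaussian_blur_rgb <- function(img, sigma) {
  out <- img
  for (ch in seq_len(dim(img)[3L]))
    out[, , ch] <- as.matrix(EBImage::gblur(img[, , ch], sigma = sigma,
                                            boundary = "replicate"))
  out
}

#' Read / write image files
#'
#' `read_image` returns an RGB array `(H, W, 3)` with values 0--255;
#' `read_mask` a binary integer matrix; `write_mask` stores a `{0, 255}`
#' 8-bit PNG; `write_instance_png`/`read_instance_png` round-trip integer
#' instance labels through 16-bit PNG.
#'
#' @param path file path.
#' @return see description.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  out <- matrix(as.integer(m >= 0.5), nrow(m), ncol(m))
  out
}

#' @rdname read_image
#' @param mask binary matrix to write.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' @rdname read_image
#' @param labels integer instance-label matrix (values < 65536). The
#'   16-bit label is stored losslessly in an RGB PNG with the high byte in
#'   the red channel and the low byte in the green channel.
#' @export
write_instance_png <- function(labels, path) {
  if (max(labels) > 65535L) stop("instance labels exceed 16 bits")
  img <- array(0, dim = c(nrow(labels), ncol(labels), 3L))
  img[, , 1L] <- (labels %/% 256L) / 255
  img[, , 2L] <- (labels %% 256L) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_instance_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 2L) {
    out <- round(m * 255)                      # plain 8-bit label image
  } else {
    out <- round(m[, , 1L] * 255) * 256L + round(m[, , 2L] * 255)
  }
  matrix(as.integer(out), nrow(m), ncol(m))
}

# manifest helpers: accept a data.frame (with "dir" attribute) or a path
# to a manifest.csv; returns the data.frame with the attribute set
load_manifest <- function(manifest, dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1L) {
    dir <- if (is.null(dir)) dirname(manifest) else dir
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(dir)) dir <- attr(manifest, "dir")
  if (is.null(dir)) stop("cannot locate the dataset directory for manifest")
  attr(manifest, "dir") <- dir
  manifest
}
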