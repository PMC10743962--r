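#' Read a radiograph or mask image as a numeric matrix
#'
#' Reads PNG/TIFF/JPEG via EBImage and returns a plain numeric matrix in
#' (row, col) orientation. Grayscale files come back as a single matrix on
#' the 0-255 scale; RGB files come back as a (row, col, 3) array so that
#' [toWeightedGray()] can be applied.
#'
#' @param path file path.
#' @return numeric matrix (grayscale) or 3-d array (RGB), intensities 0-255.
#' @export
readSpineImage <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) return(t(d) * 255)
  nch <- dim(d)[3]
  if (nch == 1L) return(t(d[, , 1]) * 255)
  out <- array(0, c(dim(d)[2], dim(d)[1], 3L))
  for (k in 1:3) out[, , k] <- t(d[, , k]) * 255
  out
}

#' Write a numeric matrix as an 8-bit grayscale image
#'
#' Values are clipped to \[0, 255\] and quantized to 8 bits at write time;
#' all in-memory processing stays in floating point.
#'
#' @param image numeric matrix, (row, col) orientation, 0-255 scale.
#' @param path output path; format follows the file extension (.png/.tiff).
#' @return `path`, invisibly.
#' @export
writeSpineImage <- function(image, path) {
  m <- .clip(image, 0, 255) / 255
  EBImage::writeImage(EBImage::Image(t(m)), path, bits.per.sample = 8L)
  invisible(path)
}
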