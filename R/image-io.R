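#' Read a PNG image
#'
#' Images are represented in memory as base-R numeric arrays with intensities
#' on the 0--255 scale: a `height x width` matrix for greyscale, or a
#' `height x width x 3` array for RGB. Pixel `(x, y)` in the screen
#' convention (origin at the upper-left corner, `x` growing rightward and
#' `y` downward, 0-based) maps to `img[y + 1, x + 1]`.
#'
#' Greyscale+alpha and RGBA files are accepted; the alpha channel is
#' dropped. Only 8-bit non-interlaced PNGs are supported.
#'
#' @param path path to a PNG file.
#' @return a numeric matrix (grey) or `h x w x 3` array (RGB).
#' @export
read_image <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("image file not found: ", path)
  raw <- .png_read_cpp(path.expand(path))
  h <- raw$height
  w <- raw$width
  ch <- raw$channels
  arr <- array(raw$data, dim = c(h, w, ch))
  if (ch == 1L) arr[, , 1L]
  else if (ch == 2L) arr[, , 1L]          # grey + alpha
  else arr[, , 1:3]                       # RGB / RGBA
}

#' Write a PNG image
#'
#' @param img greyscale matrix or `h x w x 3` RGB array, intensities 0--255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.matrix(img)) {
    .png_write_cpp(path.expand(path), as.numeric(img),
                   ncol(img), nrow(img), 1L)
  } else if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L) {
    .png_write_cpp(path.expand(path), as.numeric(img),
                   dim(img)[2], dim(img)[1], 3L)
  } else {
    stop("img must be a greyscale matrix or an h x w x 3 RGB array")
  }
  invisible(path)
}

#' Convert an image to greyscale
#'
#' RGB images are reduced with the Rec. 601 luminance weights
#' (0.299, 0.587, 0.114); greyscale input is returned unchanged.
#'
#' @param img image matrix or RGB array.
#' @return greyscale matrix.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (is.array(img) && length(dim(img)) == 3L)
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  stop("not an image")
}

# load a file straight to a greyscale matrix
load_image_gray <- function(path) to_gray(read_image(path))

# expand a greyscale matrix to RGB for overlay drawing
gray_to_rgb <- function(img) {
  if (!is.matrix(img)) return(img)
  array(rep(img, 3L), dim = c(nrow(img), ncol(img), 3L))
}
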