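#' Grayscale image container
#'
#' A `gray_image` is an integer matrix of pixel intensities in
#' `[0, levels - 1]` (row = i, column = j), the unit every enhancer in this
#' package consumes and produces. The constructor validates range and
#' dimensions; arithmetic on the underlying matrix is unrestricted.
#'
#' @param pixels numeric matrix (or object coercible to one) of intensities.
#'   Values must be whole numbers in `[0, levels - 1]`.
#' @param levels number of gray levels `G` (default 256 for 8-bit images).
#' @return an integer matrix of class `gray_image` with attribute `levels`.
#' @examples
#' img <- gray_image(matrix(0:254, 15, 17))
#' range(img)
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  levels <- as.integer(levels)
  if (length(levels) != 1L || is.na(levels) || levels < 2L)
    stop_invalid("`levels` must be a single integer >= 2")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_invalid("image must have height >= 1 and width >= 1")
  if (anyNA(pixels)) stop_invalid("image contains missing pixel values")
  if (any(pixels != round(pixels)))
    stop_invalid("pixel values must be whole numbers")
  if (any(pixels < 0) || any(pixels > levels - 1L))
    stop_invalid(sprintf("pixel values must lie in [0, %d]", levels - 1L))
  storage.mode(pixels) <- "integer"
  structure(pixels, levels = levels, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d levels, range [%d, %d]>\n",
              nrow(x), ncol(x), gray_levels(x), min(x), max(x)))
  invisible(x)
}

#' Number of gray levels of an image
#'
#' @param image a [gray_image()] (plain matrices are assumed 8-bit).
#' @return integer `G`.
#' @export
gray_levels <- function(image) {
  lv <- attr(image, "levels")
  if (is.null(lv)) 256L else as.integer(lv)
}

# Validate-or-coerce helper used by every operation taking an image.
as_gray_image <- function(image, levels = NULL) {
  if (inherits(image, "gray_image") && is.null(levels)) return(image)
  gray_image(image, levels %||% gray_levels(image))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an 8-bit grayscale PNG
#'
#' Color PNGs are rejected: convert to single-channel grayscale first.
#' Channel values are mapped to integers in `[0, 255]`.
#'
#' @param path file path of the PNG.
#' @return a [gray_image()].
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop_file(sprintf("file not found: %s", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3L]
    rgb <- a[, , seq_len(min(nch, 3L)), drop = FALSE]
    if (any(rgb != rgb[, , 1L]))
      stop_invalid(paste0("color image: convert to single-channel grayscale ",
                          "first (e.g. with an image tool), then retry"))
    a <- a[, , 1L]
  }
  gray_image(round(a * 255), levels = 256L)
}

#' Write an image as 8-bit single-channel PNG
#'
#' @param image a [gray_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  image <- as_gray_image(image)
  g <- gray_levels(image)
  png::writePNG(unclass(image) / (g - 1), target = path)
  invisible(path)
}

#' Gray-level histogram of an image
#'
#' Exact per-level pixel counts; counts always sum to the pixel count.
#'
#' @param image a [gray_image()].
#' @return object of class `gray_histogram`: list with integer `counts`
#'   (length `G`, index 1 = level 0) and `levels`.
#' @examples
#' h <- gray_histogram(gray_image(matrix(7L, 2, 2)))
#' h$counts[8]  # level 7 occupies all four pixels
#' @export
gray_histogram <- function(image) {
  image <- as_gray_image(image)
  g <- gray_levels(image)
  counts <- tabulate(as.integer(image) + 1L, nbins = g)
  structure(list(counts = counts, levels = g), class = "gray_histogram")
}

#' Shannon entropy of a gray-level histogram, in bits
#'
#' Zero-count levels contribute nothing; the value lies in `[0, log2(G)]` and
#' is maximal only for the flat histogram.
#'
#' @param hist a `gray_histogram`, or a [gray_image()] (its histogram is
#'   taken first).
#' @return entropy in bits.
#' @examples
#' entropy_bits(gray_histogram(gray_image(matrix(c(0, 0, 0, 1), 2, 2))))
#' @export
entropy_bits <- function(hist) {
  if (inherits(hist, "gray_image") || is.matrix(hist))
    hist <- gray_histogram(hist)
  if (!inherits(hist, "gray_histogram"))
    stop_invalid("`hist` must be a gray_histogram or gray_image")
  n <- sum(hist$counts)
  if (n <= 0) stop_invalid("empty histogram: no pixels counted")
  p <- hist$counts[hist$counts > 0] / n
  -sum(p * log2(p))
}

# round half up: the fixed rounding rule wherever a real maps to a gray level
round_half_up <- function(x) floor(x + 0.5)

# classed conditions -----------------------------------------------------

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("sonopcnn_invalid_input",
                                     "sonopcnn_error")))
}

stop_param <- function(msg) {
  stop(errorCondition(msg, class = c("sonopcnn_invalid_param",
                                     "sonopcnn_error")))
}

stop_file <- function(msg) {
  stop(errorCondition(msg, class = c("sonopcnn_file_error", "sonopcnn_error")))
}

stop_domain <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sonopcnn_error")))
}
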