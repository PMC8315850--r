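#' Global histogram equalization
#'
#' Classic cumulative-distribution remap: level `v` maps to
#' `round(cdf(v) * (G - 1))` with round-half-up, where `cdf` is the empirical
#' CDF of the gray-level histogram. The level map is monotone non-decreasing,
#' so relative ordering of distinct input levels is preserved. No min-CDF
#' offset correction is applied.
#'
#' @param image a [gray_image()].
#' @return the equalized [gray_image()].
#' @examples
#' img <- gray_image(matrix(c(rep(0L, 10), rep(128L, 4), rep(255L, 2)), 4, 4))
#' sort(unique(as.integer(hist_equalize(img))))
#' @export
hist_equalize <- function(image) {
  image <- as_gray_image(image)
  g <- gray_levels(image)
  counts <- gray_histogram(image)$counts
  cdf <- cumsum(counts) / sum(counts)
  map <- round_half_up(cdf * (g - 1))
  gray_image(matrix(map[as.integer(image) + 1L], nrow(image), ncol(image)),
             levels = g)
}

#' Linear contrast stretch
#'
#' Affine remap sending `low -> 0` and `high -> G - 1`, values outside
#' `[low, high]` clipped, round-half-up. Defaults stretch the image's own
#' min/max to the full range.
#'
#' @param image a [gray_image()].
#' @param low,high stretch endpoints; `low < high` required.
#' @return the stretched [gray_image()].
#' @examples
#' linear_transform(gray_image(matrix(128L, 1, 1)), low = 0, high = 200)
#' @export
linear_transform <- function(image, low = NULL, high = NULL) {
  image <- as_gray_image(image)
  g <- gray_levels(image)
  low <- low %||% min(image)
  high <- high %||% max(image)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop_param("`low` must be strictly less than `high`")
  x <- pmin(pmax(unclass(image), low), high)
  out <- round_half_up((x - low) / (high - low) * (g - 1))
  gray_image(out, levels = g)
}

# chi-square distance of the histogram to the flat histogram, normalized to
# [0, 1]: 0 = perfectly flat, 1 = all mass on a single level.
hist_uniformity_score <- function(hist) {
  n <- sum(hist$counts)
  g <- hist$levels
  e <- n / g
  chisq <- sum((hist$counts - e)^2 / e)
  chisq / (n * (g - 1))
}

#' Compare the three enhancement methods on one image
#'
#' Runs histogram equalization, linear stretch and the PCNN enhancer on the
#' same input and scores each output with the histogram/information metrics:
#' Shannon entropy (bits), dynamic-range fraction `(max - min)/(G - 1)`, and
#' the normalized chi-square distance to the flat histogram (0 = flat).
#' These quantify the visual comparison the three methods are usually given.
#'
#' @param image a [gray_image()].
#' @param params a [pcnn_params()] for the PCNN method.
#' @return data.frame with one row per method (`hist_eq`, `linear`, `pcnn`,
#'   sorted by name) and columns `method`, `entropy_bits`,
#'   `dynamic_range`, `uniformity`.
#' @export
compare_methods <- function(image, params = pcnn_params()) {
  image <- as_gray_image(image)
  g <- gray_levels(image)
  enhanced <- list(
    hist_eq = hist_equalize(image),
    linear = linear_transform(image),
    pcnn = pcnn_enhance(image, params)
  )
  enhanced <- enhanced[order(names(enhanced))]
  rows <- lapply(names(enhanced), function(nm) {
    out <- enhanced[[nm]]
    h <- gray_histogram(out)
    data.frame(method = nm,
               entropy_bits = entropy_bits(h),
               dynamic_range = (max(out) - min(out)) / (g - 1),
               uniformity = hist_uniformity_score(h),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
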