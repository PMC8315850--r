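#' PCNN parameter set
#'
#' All constants of the fire-once pulse-coupled neural network enhancer.
#' Defaults are the published operating point: link strength `alpha = 0.2`,
#' threshold attenuation `tau = 0.7`, linking amplitude `w_l = 1` and
#' re-excitation amplitude `w_f = 278`. `w_f` is retained for fidelity to the
#' published update rule but is inert here: a fired neuron's threshold is the
#' `+Inf` sentinel, so adding `w_f * Y` never changes it.
#'
#' @param alpha link-strength constant (dimensionless, >= 0). `alpha = 0`
#'   decouples the network into independent per-pixel recurrences.
#' @param tau threshold attenuation constant per iteration (> 0); unfired
#'   thresholds decay by `exp(-tau)` each cycle.
#' @param w_l linking amplitude applied to the neighborhood feedback sum.
#' @param w_f amplitude added to a neuron's threshold on firing (> 0).
#' @param laplacian_center center weight of the 3x3 Laplacian used for
#'   threshold initialization; all eight off-center weights are -1. The
#'   standard zero-sum kernel has center 8.
#' @param linking_kernel 3x3 nonnegative neighbor weights `V`; default is the
#'   uniform 8-neighborhood (ones, zero center).
#' @param max_iters iteration cap `M` (>= 1). Exceeding it raises an
#'   iteration-cap error naming the unfired count.
#' @param stimulus_floor small positive value substituted for zero stimuli
#'   and for non-positive initial thresholds; guarantees termination.
#' @param tau_enh decay constant of the firing-time-to-gray map; independent
#'   of the iteration `tau`, same default.
#' @param enhance_form `"exp"` (default) maps firing times through
#'   `BPG * exp(-tau_enh * (S - 1))`; `"log"` uses the literal logarithmic
#'   reading `ln(BPG) - tau_enh * (S - 1)`. Both are strictly decreasing in S
#'   and order-equivalent after rescaling.
#' @return list of class `pcnn_params`.
#' @examples
#' p <- pcnn_params()
#' p$alpha; p$tau
#' @export
pcnn_params <- function(alpha = 0.2, tau = 0.7, w_l = 1, w_f = 278,
                        laplacian_center = 8, linking_kernel = NULL,
                        max_iters = 64L, stimulus_floor = 1,
                        tau_enh = 0.7, enhance_form = c("exp", "log")) {
  enhance_form <- match.arg(enhance_form)
  if (is.null(linking_kernel)) {
    linking_kernel <- matrix(1, 3, 3)
    linking_kernel[2, 2] <- 0
  }
  linking_kernel <- as.matrix(linking_kernel)
  if (!all(dim(linking_kernel) == c(3L, 3L)) || any(linking_kernel < 0))
    stop_param("`linking_kernel` must be a 3x3 nonnegative matrix")
  for (nm in c("alpha", "tau", "w_l", "w_f", "laplacian_center",
               "max_iters", "stimulus_floor", "tau_enh")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v))
      stop_param(sprintf("`%s` must be a single finite number", nm))
  }
  if (alpha < 0) stop_param("`alpha` must be >= 0")
  if (tau <= 0) stop_param("`tau` must be > 0")
  if (w_f <= 0) stop_param("`w_f` must be > 0")
  if (tau_enh <= 0) stop_param("`tau_enh` must be > 0")
  if (max_iters < 1) stop_param("`max_iters` must be >= 1")
  if (stimulus_floor <= 0) stop_param("`stimulus_floor` must be > 0")
  structure(list(alpha = alpha, tau = tau, w_l = w_l, w_f = w_f,
                 laplacian_center = laplacian_center,
                 linking_kernel = linking_kernel,
                 max_iters = as.integer(max_iters),
                 stimulus_floor = stimulus_floor,
                 tau_enh = tau_enh, enhance_form = enhance_form),
            class = "pcnn_params")
}

# 3x3 convolution with half-sample reflect padding (edge row/col duplicated).
conv3x3_reflect <- function(x, kernel) {
  nr <- nrow(x)
  nc <- ncol(x)
  pad <- x[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc), drop = FALSE]
  out <- matrix(0, nr, nc)
  for (di in 0:2) {
    for (dj in 0:2) {
      k <- kernel[di + 1L, dj + 1L]
      if (k != 0)
        out <- out + k * pad[di + seq_len(nr), dj + seq_len(nc), drop = FALSE]
    }
  }
  out
}

#' Laplacian convolution of an image
#'
#' Convolves the image with the 3x3 Laplacian whose eight off-center weights
#' are -1 and whose center weight is `center`; borders use reflect padding.
#' The output is real-valued and not clamped.
#'
#' @param image a [gray_image()].
#' @param center center weight (8 gives the zero-sum kernel).
#' @return numeric matrix of the image's shape.
#' @examples
#' laplacian_convolve(gray_image(matrix(50L, 3, 3)), center = 8)  # all zero
#' @export
laplacian_convolve <- function(image, center = 8) {
  image <- as_gray_image(image)
  kernel <- matrix(-1, 3, 3)
  kernel[2, 2] <- center
  conv3x3_reflect(unclass(image), kernel)
}

#' Initial dynamic thresholds from the Laplacian field
#'
#' Each neuron's starting threshold is `BPG - CPG(i, j)`, where `BPG` is the
#' brightest pixel of the input and `CPG` the Laplacian-convolved gray value,
#' clamped below at `stimulus_floor` so every threshold is positive and
#' reachable by exponential decay. On flat regions the zero-sum kernel leaves
#' thresholds at `BPG`, so relative firing order encodes local contrast
#' (Mach-band-style edge exaggeration).
#'
#' @param image a [gray_image()].
#' @param params a [pcnn_params()].
#' @return numeric matrix of strictly positive finite thresholds.
#' @export
init_thresholds <- function(image, params = pcnn_params()) {
  image <- as_gray_image(image)
  cpg <- laplacian_convolve(image, params$laplacian_center)
  bpg <- max(image)
  pmax(bpg - cpg, params$stimulus_floor)
}

#' Run the fire-once PCNN and record firing times
#'
#' Synchronous iterations `m = 1, 2, ...`: the feed input `F` is the pixel
#' stimulus (floored at `stimulus_floor`, constant across iterations); the
#' link `R = w_l * sum(V * Y[m-1])` over the 3x3 neighborhood (reflect
#' padding); internal activity `U = F * (1 + alpha * R)`. At the start of
#' each iteration every unfired threshold decays by `exp(-tau)`; a neuron
#' fires when `U` exceeds its threshold, its firing time is recorded in `S`
#' and its threshold becomes `+Inf` so it can never re-ignite. The loop ends
#' when all neurons have fired.
#'
#' @param image a [gray_image()].
#' @param params a [pcnn_params()].
#' @param verbose if `TRUE`, message the fired-neuron count each iteration.
#' @return integer matrix `S` of class `firing_times` (values in
#'   `[1, max_iters]`), with attribute `iterations` = last iteration used.
#' @examples
#' run_pcnn(gray_image(matrix(200L, 1, 1)))  # fires at m = 1
#' @export
run_pcnn <- function(image, params = pcnn_params(), verbose = FALSE) {
  image <- as_gray_image(image)
  px <- unclass(image)
  stim <- pmax(px, params$stimulus_floor)
  theta <- init_thresholds(image, params)
  nr <- nrow(px)
  nc <- ncol(px)
  s <- matrix(NA_integer_, nr, nc)
  fired <- matrix(FALSE, nr, nc)
  y <- matrix(0, nr, nc)
  decay <- exp(-params$tau)
  for (m in seq_len(params$max_iters)) {
    theta <- decay * theta + params$w_f * y  # +Inf sentinel absorbs both terms
    if (params$alpha > 0 && any(y > 0)) {
      r <- params$w_l * conv3x3_reflect(y, params$linking_kernel)
      u <- stim * (1 + params$alpha * r)
    } else {
      u <- stim
    }
    new <- !fired & (u > theta)
    if (any(new)) {
      s[new] <- m
      fired[new] <- TRUE
      theta[new] <- Inf
    }
    y <- new + 0
    if (verbose) message(sprintf("iteration %d: %d neuron(s) fired", m, sum(new)))
    if (all(fired)) {
      return(structure(s, iterations = m,
                       class = c("firing_times", "matrix", "array")))
    }
  }
  stop_domain(sprintf(
    "PCNN did not terminate: %d neuron(s) unfired after %d iterations",
    sum(!fired), params$max_iters), "sonopcnn_iteration_cap")
}

#' @export
print.firing_times <- function(x, ...) {
  cat(sprintf("<firing_times %d x %d, S in [%d, %d], %d iterations>\n",
              nrow(x), ncol(x), min(x), max(x), attr(x, "iterations")))
  invisible(x)
}

#' Map firing times to an enhanced gray image
#'
#' Early-firing neurons correspond to locally salient, bright structure:
#' the raw value `BPG * exp(-tau_enh * (S - 1))` (or the logarithmic form,
#' see [pcnn_params()]) is strictly decreasing in the firing time, then
#' min-max rescaled onto `[0, G - 1]` with round-half-up. A constant firing
#' field maps to mid-gray `floor((G - 1) / 2)` by convention.
#'
#' @param image the input [gray_image()] (supplies `BPG` and `G`).
#' @param firing a `firing_times` matrix from [run_pcnn()].
#' @param params a [pcnn_params()].
#' @return the enhanced [gray_image()].
#' @export
enhance <- function(image, firing, params = pcnn_params()) {
  image <- as_gray_image(image)
  if (!all(dim(firing) == dim(image)))
    stop_invalid("firing-time matrix shape does not match the image")
  if (anyNA(firing) || any(firing < 1))
    stop_invalid("firing times must all be >= 1")
  bpg <- max(image)
  if (bpg <= 0)
    stop_invalid("all-black image: BPG must be > 0 to enhance")
  g <- gray_levels(image)
  s <- unclass(firing)
  raw <- switch(params$enhance_form,
                exp = bpg * exp(-params$tau_enh * (s - 1)),
                log = log(bpg) - params$tau_enh * (s - 1))
  lo <- min(raw)
  hi <- max(raw)
  out <- if (hi > lo) {
    round_half_up((raw - lo) / (hi - lo) * (g - 1))
  } else {
    matrix(floor((g - 1) / 2), nrow(s), ncol(s))
  }
  gray_image(out, levels = g)
}

#' Full PCNN enhancement pipeline
#'
#' `enhance(image, run_pcnn(image, params), params)`: deterministic, no
#' randomness anywhere.
#'
#' @inheritParams run_pcnn
#' @return the enhanced [gray_image()].
#' @examples
#' img <- gray_image(matrix(c(60L, 80L, 100L, 120L), 2, 2))
#' pcnn_enhance(img)
#' @export
pcnn_enhance <- function(image, params = pcnn_params(), verbose = FALSE) {
  image <- as_gray_image(image)
  enhance(image, run_pcnn(image, params, verbose = verbose), params)
}
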