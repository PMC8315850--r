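# Independent oracles used across the suite. These deliberately share no
# code with the package: direct loops, brute-force enumeration, closed forms.

rand_image <- function(h, w, seed, levels = 256L) {
  withr::with_seed(seed,
    gray_image(matrix(sample.int(levels, h * w, replace = TRUE) - 1L, h, w),
               levels = levels))
}

# direct sliding-window 3x3 convolution; for a 1-pixel border, half-sample
# reflect padding coincides with nearest-edge index clamping
conv3x3_oracle <- function(px, kernel) {
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- min(max(i + di, 1L), nr)
          jj <- min(max(j + dj, 1L), nc)
          acc <- acc + kernel[di + 2L, dj + 2L] * px[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

laplacian_kernel <- function(center) {
  k <- matrix(-1, 3, 3)
  k[2, 2] <- center
  k
}

# per-pixel scalar recurrence: first m >= 1 with stim > exp(-tau*m) * theta0
pcnn_scalar_oracle <- function(stim, theta0, tau, max_iters) {
  theta <- theta0
  for (m in seq_len(max_iters)) {
    theta <- exp(-tau) * theta
    if (stim > theta) return(m)
  }
  NA_integer_
}

# all-pairs Mann-Whitney statistic: concordant + half ties over all pairs
auc_bruteforce <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
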