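test_that("laplacian_convolve matches closed forms and the sliding-window oracle", {
  const <- gray_image(matrix(50L, 3, 3))
  expect_equal(laplacian_convolve(const, center = 8), matrix(0, 3, 3))
  expect_equal(laplacian_convolve(const, center = 6), matrix(-100, 3, 3))

  # single bright interior pixel: center 8*100, 8-neighbors -100, elsewhere 0
  px <- matrix(0L, 5, 5)
  px[3, 3] <- 100L
  got <- laplacian_convolve(gray_image(px), center = 8)
  want <- matrix(0, 5, 5)
  want[2:4, 2:4] <- -100
  want[3, 3] <- 800
  expect_equal(got, want)

  for (seed in 1:5) {
    img <- rand_image(6, 9, seed)
    expect_equal(laplacian_convolve(img, 8),
                 conv3x3_oracle(unclass(img), laplacian_kernel(8)))
  }
  expect_error(gray_image(matrix(integer(0), 0, 3)), class = "sonopcnn_invalid_input")
})

test_that("init_thresholds is BPG minus the convolution, clamped at the floor", {
  p <- pcnn_params()
  const <- gray_image(matrix(50L, 4, 4))
  expect_equal(init_thresholds(const, p), matrix(50, 4, 4))

  # bright isolated pixel: CPG = 1600 > BPG = 200, raw threshold negative
  px <- matrix(0L, 3, 3)
  px[2, 2] <- 200L
  th <- init_thresholds(gray_image(px), p)
  expect_equal(th[2, 2], p$stimulus_floor)
  expect_true(all(th > 0) && all(is.finite(th)))

  ramp <- gray_image(matrix(seq(0L, 150L, by = 10L), 4, 4))
  want <- pmax(150 - conv3x3_oracle(unclass(ramp), laplacian_kernel(8)),
               p$stimulus_floor)
  expect_equal(init_thresholds(ramp, p), want)
})

test_that("run_pcnn: scalar case, symmetry, and fire-once bookkeeping", {
  s <- run_pcnn(gray_image(matrix(200L, 1, 1)))
  expect_equal(unclass(s), matrix(1L, 1, 1), ignore_attr = TRUE)

  # constant image: every neuron is in an identical state, all fire together
  s <- run_pcnn(gray_image(matrix(90L, 5, 7)))
  expect_length(unique(as.integer(s)), 1L)

  img <- rand_image(10, 10, seed = 42)
  s <- run_pcnn(img)
  expect_false(anyNA(s))
  expect_true(all(s >= 1L & s <= pcnn_params()$max_iters))
  expect_equal(sum(table(as.integer(s))), length(img))
})

test_that("run_pcnn with alpha = 0 equals the per-pixel scalar recurrence", {
  p <- pcnn_params(alpha = 0)
  for (seed in 1:10) {
    img <- rand_image(8, 8, seed)
    s <- run_pcnn(img, p)
    theta0 <- pmax(max(img) - conv3x3_oracle(unclass(img), laplacian_kernel(8)),
                   p$stimulus_floor)
    stim <- pmax(unclass(img), p$stimulus_floor)
    want <- matrix(mapply(pcnn_scalar_oracle, stim, theta0,
                          MoreArgs = list(tau = p$tau, max_iters = p$max_iters)),
                   8, 8)
    expect_equal(unclass(s), want, ignore_attr = TRUE)
  }
})

test_that("run_pcnn raises the iteration-cap error naming the unfired count", {
  ph <- make_phantom(phantom_spec(height = 16, width = 16, axes = c(6, 4),
                                  seed = 2))
  expect_true(attr(run_pcnn(ph), "iterations") > 1L)
  err <- expect_error(run_pcnn(ph, pcnn_params(max_iters = 1L)),
                      class = "sonopcnn_iteration_cap")
  expect_match(conditionMessage(err), "[0-9]+ neuron")
})

test_that("enhance maps firing times to gray levels per the closed form", {
  ft <- function(m) structure(m, class = c("firing_times", "matrix", "array"))
  img <- gray_image(matrix(c(100L, 50L, 25L), 3, 1))
  # raw = 100 * exp(-0.7 * (S - 1)) = (100, 49.66, 24.66) -> (255, 85, 0)
  expect_equal(as.integer(enhance(img, ft(matrix(1:3, 3, 1)))), c(255L, 85L, 0L))
  # S = 1 is the brightest output level
  out <- enhance(img, ft(matrix(c(1L, 4L, 2L), 3, 1)))
  expect_equal(as.integer(out)[1], 255L)
  # degenerate constant firing field -> mid-gray
  expect_equal(as.integer(enhance(img, ft(matrix(2L, 3, 1)))), rep(127L, 3))
  expect_error(enhance(img, ft(matrix(c(0L, 1L, 2L), 3, 1))),
               class = "sonopcnn_invalid_input")

  # strict anti-monotonicity in S, preserved by rescaling; log form agrees
  s <- matrix(c(1L, 2L, 3L, 5L, 8L), 5, 1)
  for (form in c("exp", "log")) {
    v <- as.integer(enhance(gray_image(matrix(200L, 5, 1)), ft(s),
                            pcnn_params(enhance_form = form)))
    expect_true(all(diff(v) < 0))
  }
})

test_that("pcnn_enhance is deterministic and respects symmetry", {
  img <- rand_image(12, 12, seed = 7)
  expect_identical(pcnn_enhance(img), pcnn_enhance(img))
  const <- pcnn_enhance(gray_image(matrix(80L, 4, 4)))
  expect_length(unique(as.integer(const)), 1L)
})

test_that("monotonicity with alpha = 0: brighter never fires later at equal thresholds", {
  p <- pcnn_params(alpha = 0)
  for (seed in 1:5) {
    img <- rand_image(8, 8, seed, levels = 16L)  # few levels force collisions
    th <- init_thresholds(img, p)
    s <- as.integer(run_pcnn(img, p))
    v <- as.integer(img)
    brighter <- outer(v, v, ">")
    th_le <- outer(as.numeric(th), as.numeric(th), "<=")
    not_later <- outer(s, s, "<=")
    expect_true(all(not_later[brighter & th_le]))
  }
})
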