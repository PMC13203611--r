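# Frequency-domain decomposition.

test_that("low plus high reconstructs the image exactly", {
  set.seed(8)
  img <- matrix(runif(64 * 48), 64, 48)
  for (m in c("fourier", "gaussian")) {
    fd <- freq_decompose(img, method = m)
    expect_lt(max(abs(fd$low + fd$high - img)), 1e-9)
  }
  expect_error(freq_decompose(array(0, c(4, 4, 3))), "single-channel")
})

test_that("a constant image has no high-frequency content", {
  img <- matrix(3.7, 32, 32)
  fd <- freq_decompose(img)
  expect_lt(max(abs(fd$high)), 1e-9)
})

test_that("variance separates onto the expected bands", {
  # coarse blob on the left half, fine checkerboard on the right half
  img <- matrix(0, 64, 64)
  yy <- matrix(rep(1:64, 64), 64); xx <- t(yy)
  img[, 1:32] <- exp(-((yy[, 1:32] - 32)^2 + (xx[, 1:32] - 16)^2) / 200)
  img[, 33:64] <- 0.5 * ((yy[, 33:64] + xx[, 33:64]) %% 2)
  fd <- freq_decompose(img, cutoff = 0.2)
  v <- function(m) stats::var(as.numeric(m))
  # high-frequency variance concentrates on the checkerboard side
  expect_gt(v(fd$high[, 33:64]), 10 * v(fd$high[, 1:32]))
  # low-frequency variance concentrates on the blob side
  expect_gt(v(fd$low[, 1:32]), 10 * v(fd$low[, 33:64]))
})
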