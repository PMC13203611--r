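# Dual-frequency feature machinery.

test_that("channel split follows round(alpha C) with recoverable totals", {
  x <- array(rnorm(8 * 8 * 64), c(8, 8, 64))
  sp <- split_channels(x, 0.5)
  expect_equal(dim(sp$high)[3], 32)
  expect_equal(dim(sp$low)[3], 32)
  expect_equal(dim(sp$low)[1:2], c(4, 4))
  sp0 <- split_channels(x, 0)
  expect_null(sp0$low)
  expect_equal(dim(sp0$high)[3], 64)
  x48 <- array(rnorm(8 * 8 * 48), c(8, 8, 48))
  sp4 <- split_channels(x48, 0.4)
  expect_equal(dim(sp4$low)[3], 19)
  expect_equal(dim(sp4$high)[3], 29)
  # groups always recover C over a grid
  for (C in 8:64) for (a in c(0.2, 0.4, 0.5, 0.6, 0.8)) {
    xl <- sonolite:::low_channels(C, a)
    expect_true(xl >= 1 && C - xl >= 1)
    expect_equal(xl + (C - xl), C)
  }
  expect_error(split_channels(x, 1.2), "alpha")
  expect_error(split_channels(array(0, c(4, 4, 2)), 0.1), "too small")
})

test_that("alpha = 0 octave blocks reduce bitwise to plain blocks", {
  set.seed(3)
  H <- 16L
  ctx1 <- sonolite:::new_net_ctx(TRUE)
  oc <- sonolite:::o_conv(ctx1, 6L, 8L, 3L, 1L, c(H, H), 0, 0)
  ctx2 <- sonolite:::new_net_ctx(TRUE)
  pc <- sonolite:::base_conv(ctx2, 6L, 8L, 3L, 1L, c(H, H))
  # copy weights
  ctx2$mods[[1]]$w <- ctx1$mods[[1]]$w
  ctx2$mods[[2]]$g <- ctx1$mods[[2]]$g
  ctx2$mods[[2]]$b <- ctx1$mods[[2]]$b
  x <- array(runif(H * H * 6), c(H, H, 6))
  f_reset(0L)
  hx <- f_from_dbl(x, H, H, 6L, 0L)
  y1 <- f_to_dbl(oc$fw(list(h = hx, l = NULL))$h)
  y2 <- f_to_dbl(pc$fw(hx))
  expect_identical(y1, y2)
})

test_that("octave paths on constant input match the summed plain kernel", {
  # away from padding borders, nearest upsampling and average pooling of a
  # constant field are exact, so the high output equals the constant times
  # the summed H->H and L->H kernel weights
  set.seed(4)
  ctx <- sonolite:::new_net_ctx(TRUE)
  oc <- sonolite:::o_conv(ctx, 4L, 4L, 3L, 1L, c(8L, 8L), 0.5, 0.5,
                          bnmode = "group")
  cval <- 0.7
  x <- array(cval, c(8, 8, 4))
  sp <- split_channels(x, 0.5)
  f_reset(0L)
  hh <- f_from_dbl(sp$high, 8L, 8L, 2L, 0L)
  hl <- f_from_dbl(sp$low, 4L, 4L, 2L, 0L)
  # bypass the normalisation: read the raw path convolutions
  hh_m <- ctx$mods[[1]]; hl_m <- ctx$mods[[2]]
  lh_m <- ctx$mods[[3]]; ll_m <- ctx$mods[[4]]
  yh <- f_to_dbl(hh_m$fw(hh))
  yl <- f_to_dbl(lh_m$fw(hl))
  # high-res interior cell (4,4) pairs with low-res interior cell (2,2)
  got <- yh[4, 4, ] + yl[2, 2, ]
  want <- cval * (colSums(hh_m$w) + colSums(lh_m$w))
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("whole-model gradients agree with finite differences", {
  set.seed(42)
  cfg <- model_config("tiny-lite")
  md <- build_detector(cfg, c(64L, 64L), seed = 42)
  for (m in md$ctx$mods) if (identical(m$kind, "norm")) m$mom <- 0
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  set.seed(7)
  wts <- NULL
  loss_of <- function() {
    out <- md$forward(x, training = TRUE)
    v <- unlist(out)
    if (is.null(wts)) wts <<- rnorm(length(v))
    sum(v * wts)
  }
  loss_of()
  out <- md$forward(x, TRUE)
  idx <- 0
  dout <- lapply(out, function(o) {
    r <- list()
    for (nm in c("cls", "reg", "obj")) {
      n <- length(o[[nm]])
      r[[nm]] <- array(wts[idx + seq_len(n)], dim(o[[nm]]))
      idx <<- idx + n
    }
    r
  })
  md$backward(dout)
  set.seed(123)
  dirs <- lapply(md$ctx$mods, function(m) {
    r <- list()
    for (f in intersect(c("w", "g", "b"), ls(m))) {
      v <- m[[f]]
      r[[f]] <- array(rnorm(length(v)), dim(as.array(v)))
    }
    r
  })
  gmap <- c(w = "gw", g = "gg", b = "gb")
  ana <- 0
  for (i in seq_along(md$ctx$mods)) {
    m <- md$ctx$mods[[i]]
    for (f in names(dirs[[i]])) ana <- ana + sum(m[[gmap[f]]] * dirs[[i]][[f]])
  }
  nrm <- sqrt(sum(vapply(dirs, function(dd)
    sum(vapply(dd, function(d) sum(d^2), numeric(1))), numeric(1))))
  dirs <- lapply(dirs, function(dd) lapply(dd, function(d) d / nrm))
  ana <- ana / nrm
  bump <- function(s) for (i in seq_along(md$ctx$mods)) {
    m <- md$ctx$mods[[i]]
    for (f in names(dirs[[i]])) m[[f]] <- m[[f]] + s * dirs[[i]][[f]]
  }
  eps <- 2e-2
  bump(eps); lp <- loss_of(); bump(-2 * eps); lm <- loss_of(); bump(eps)
  num <- (lp - lm) / (2 * eps)
  expect_lt(abs(ana - num) / max(abs(ana), abs(num)), 0.02)
})
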