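# Module system for the CPU conv-net engine.
#
# Tensors are handles into a float32 arena runtime (src/float_rt.cpp):
# c(arena, offset, H, W, C). Arena 0 holds forward activations (reset at the
# start of each forward pass; they survive through the following backward
# pass as caches), arena 1 holds gradients (reset at the start of each
# backward pass). Weights and gradients are R double arrays owned by the
# leaf modules: the optimiser and serialisation work in double precision,
# kernels convert on the fly.
#
# A "net context" collects every parameterised leaf module and a symbolic
# layer table used by the analytic profiler. Modules are environments with
# $fw(h) / $bw(dh); the graph is static and each module runs exactly once
# per pass, so caching inside the module is safe.

new_net_ctx <- function(alloc = TRUE) {
  ctx <- new.env(parent = emptyenv())
  ctx$alloc <- alloc
  ctx$training <- TRUE
  ctx$mods <- list()       # parameterised leaves, in registration order
  ctx$rows <- list()       # symbolic layer descriptors
  ctx
}

ctx_row <- function(ctx, kind, cin, cout, k, groups, h, w, bias = FALSE) {
  ctx$rows[[length(ctx$rows) + 1L]] <-
    list(kind = kind, cin = cin, cout = cout, k = k, groups = groups,
         h = h, w = w, bias = bias)
  invisible(NULL)
}

ctx_layer_table <- function(ctx) {
  do.call(rbind, lapply(ctx$rows, function(r) as.data.frame(r)))
}

reg_mod <- function(ctx, m) {
  ctx$mods[[length(ctx$mods) + 1L]] <- m
  invisible(m)
}

# low-frequency channel count: round(alpha * C), ties up
low_channels <- function(C, alpha) floor(alpha * C + 0.5)

h_dim <- function(h) h[3:5]

# ---- leaf modules ---------------------------------------------------------

m_conv <- function(ctx, cin, cout, k, stride, sh_in, bias = FALSE,
                   bias_init = 0) {
  sh_out <- sh_in %/% stride
  ctx_row(ctx, "conv", cin, cout, k, 1L, sh_out[1], sh_out[2], bias)
  m <- new.env(parent = emptyenv())
  m$kind <- "conv"; m$cin <- cin; m$cout <- cout; m$k <- k
  m$stride <- stride; m$pad <- (k - 1L) %/% 2L
  m$sh_in <- sh_in; m$sh_out <- sh_out; m$has_bias <- bias
  if (ctx$alloc) {
    bound <- 1 / sqrt(cin * k * k)
    m$w <- matrix(runif(k * k * cin * cout, -bound, bound), k * k * cin, cout)
    m$gw <- matrix(0, k * k * cin, cout)
    if (bias) { m$b <- rep(bias_init, cout); m$gb <- rep(0, cout) }
    m$decay <- TRUE
  }
  m$fw <- function(hx) {
    m$x <- hx
    hy <- f_conv_fw(hx, m$w, m$k, m$stride, m$pad, m$cout)
    if (m$has_bias) hy <- f_bias_add_ip(hy, m$b)
    hy
  }
  m$bw <- function(hdy) {
    if (m$has_bias) m$gb <- m$gb + f_colsum(hdy)
    f_conv_bw(hdy, m$x, m$w, m$gw, m$k, m$stride, m$pad, m$cout)
  }
  reg_mod(ctx, m)
}

m_dwconv <- function(ctx, cin, k, stride, sh_in) {
  sh_out <- sh_in %/% stride
  ctx_row(ctx, "conv", cin, cin, k, cin, sh_out[1], sh_out[2], FALSE)
  m <- new.env(parent = emptyenv())
  m$kind <- "dwconv"; m$cin <- cin; m$cout <- cin; m$k <- k
  m$stride <- stride; m$pad <- (k - 1L) %/% 2L
  m$sh_in <- sh_in; m$sh_out <- sh_out; m$has_bias <- FALSE
  if (ctx$alloc) {
    bound <- 1 / sqrt(k * k)
    m$w <- array(runif(k * k * cin, -bound, bound), c(k, k, cin))
    m$gw <- array(0, c(k, k, cin))
    m$decay <- TRUE
  }
  m$fw <- function(hx) {
    m$x <- hx
    f_dw_fw(hx, m$w, m$k, m$stride, m$pad)
  }
  m$bw <- function(hdy) {
    f_dw_bw(hdy, m$x, m$w, m$gw, m$k, m$stride, m$pad)
  }
  reg_mod(ctx, m)
}

# fused channel normalisation + SiLU (the standard conv-block tail).
# Statistics are per sample over spatial positions at training AND
# inference (instance-normalisation semantics: per-sample statistics are
# what the network was optimised under, and they are batch-independent).
# Modules on very small maps normalise with accumulated running averages
# instead, in both modes (see the methods vignette).
m_normsilu <- function(ctx, C, sh) {
  ctx_row(ctx, "norm", C, C, 0L, 1L, sh[1], sh[2], FALSE)
  m <- new.env(parent = emptyenv())
  m$kind <- "norm"; m$cin <- C; m$cout <- C; m$eps <- 1e-5; m$mom <- 0.05
  m$ctx <- ctx
  # per-sample statistics are degenerate on very small maps (pooled context
  # branches): those normalise with accumulated statistics instead
  m$frozen <- prod(sh) < 16L
  if (ctx$alloc) {
    m$g <- rep(1, C); m$b <- rep(0, C)
    m$gg <- rep(0, C); m$gb <- rep(0, C)
    m$rm <- rep(0, C); m$rv <- rep(1, C)
    m$decay <- FALSE
  }
  m$fw <- function(hz) {
    if (m$frozen && !m$ctx$training)
      return(f_ns_eval(hz, m$g, m$b, m$rm, m$rv, m$eps))
    r <- if (m$frozen) f_nsfroz_fw(hz, m$g, m$b, m$rm, m$rv, m$eps)
         else f_ns_fw(hz, m$g, m$b, m$eps)
    if (m$ctx$training) {
      m$z <- hz; m$mu <- r$mu; m$var <- r$var
      m$rm <- (1 - m$mom) * m$rm + m$mom * r$mu
      m$rv <- (1 - m$mom) * m$rv + m$mom * r$var
    }
    r$y
  }
  m$bw <- function(hdy) {
    r <- if (m$frozen) f_nsfroz_bw(hdy, m$z, m$g, m$b, m$rm, m$rv, m$eps)
         else f_ns_bw(hdy, m$z, m$mu, m$var, m$g, m$b, m$eps)
    m$gg <- m$gg + r$gg
    m$gb <- m$gb + r$gb
    r$dz
  }
  reg_mod(ctx, m)
}

# bare channel normalisation (per-path norms in cross-fusion modules)
m_norm <- function(ctx, C, sh) {
  ctx_row(ctx, "norm", C, C, 0L, 1L, sh[1], sh[2], FALSE)
  m <- new.env(parent = emptyenv())
  m$kind <- "norm"; m$cin <- C; m$cout <- C; m$eps <- 1e-5; m$mom <- 0.05
  m$ctx <- ctx
  if (ctx$alloc) {
    m$g <- rep(1, C); m$b <- rep(0, C)
    m$gg <- rep(0, C); m$gb <- rep(0, C)
    m$rm <- rep(0, C); m$rv <- rep(1, C)
    m$decay <- FALSE
  }
  m$fw <- function(hz) {
    r <- f_norm_fw(hz, m$g, m$b, m$eps, TRUE, m$rm, m$rv)
    if (m$ctx$training) {
      m$rm <- (1 - m$mom) * m$rm + m$mom * r$mu
      m$rv <- (1 - m$mom) * m$rv + m$mom * r$var
      m$z <- hz; m$mu <- r$mu; m$var <- r$var
    }
    r$y
  }
  m$bw <- function(hdy) {
    r <- f_norm_bw(hdy, m$z, m$mu, m$var, m$g, m$eps)
    m$gg <- m$gg + r$gg
    m$gb <- m$gb + r$gb
    r$dz
  }
  reg_mod(ctx, m)
}

m_silu <- function() {
  m <- new.env(parent = emptyenv())
  m$fw <- function(hx) { m$x <- hx; f_silu_fw(hx) }
  m$bw <- function(hdy) f_silu_bw(hdy, m$x)
  m
}

# ---- simple composites ----------------------------------------------------

seq_block <- function(...) {
  mods <- list(...)
  m <- new.env(parent = emptyenv())
  m$mods <- mods
  m$fw <- function(x) { for (mm in mods) x <- mm$fw(x); x }
  m$bw <- function(dy) { for (mm in rev(mods)) dy <- mm$bw(dy); dy }
  m
}

# conv + norm + SiLU
base_conv <- function(ctx, cin, cout, k, stride, sh_in) {
  sh_out <- sh_in %/% stride
  m <- seq_block(m_conv(ctx, cin, cout, k, stride, sh_in),
                 m_normsilu(ctx, cout, sh_out))
  m$cout <- cout; m$sh_out <- sh_out
  m
}

# depthwise separable: dw k x k + pw 1 x 1, each with norm + SiLU
dw_unit <- function(ctx, cin, cout, k, stride, sh_in) {
  sh_out <- sh_in %/% stride
  m <- seq_block(m_dwconv(ctx, cin, k, stride, sh_in),
                 m_normsilu(ctx, cin, sh_out),
                 m_conv(ctx, cin, cout, 1L, 1L, sh_out),
                 m_normsilu(ctx, cout, sh_out))
  m$cout <- cout; m$sh_out <- sh_out
  m
}

conv_unit <- function(ctx, cin, cout, k, stride, sh_in, depthwise = FALSE) {
  if (depthwise && k > 1L) dw_unit(ctx, cin, cout, k, stride, sh_in)
  else base_conv(ctx, cin, cout, k, stride, sh_in)
}

# stem: space-to-depth + 3x3 conv block
focus_stem <- function(ctx, cin, cout, sh_in) {
  sh_mid <- sh_in %/% 2L
  cb <- base_conv(ctx, 4L * cin, cout, 3L, 1L, sh_mid)
  m <- new.env(parent = emptyenv())
  m$cout <- cout; m$sh_out <- sh_mid
  m$fw <- function(hx) cb$fw(f_space2depth_fw(hx))
  m$bw <- function(hdy) f_space2depth_bw(cb$bw(hdy))
  m
}

bottleneck_block <- function(ctx, c, sh, shortcut = TRUE, depthwise = FALSE) {
  c1 <- base_conv(ctx, c, c, 1L, 1L, sh)
  c2 <- conv_unit(ctx, c, c, 3L, 1L, sh, depthwise)
  m <- new.env(parent = emptyenv())
  m$cout <- c; m$sh_out <- sh
  m$fw <- function(hx) {
    hy <- c2$fw(c1$fw(hx))
    if (shortcut) f_add(hy, hx) else hy
  }
  m$bw <- function(hdy) {
    hdx <- c1$bw(c2$bw(hdy))
    if (shortcut) f_add(hdx, hdy) else hdx
  }
  m
}

csp_layer <- function(ctx, cin, cout, n, sh, shortcut = TRUE,
                      depthwise = FALSE) {
  hid <- cout %/% 2L
  cv1 <- base_conv(ctx, cin, hid, 1L, 1L, sh)
  cv2 <- base_conv(ctx, cin, hid, 1L, 1L, sh)
  bns <- lapply(seq_len(n), function(i)
    bottleneck_block(ctx, hid, sh, shortcut, depthwise))
  cv3 <- base_conv(ctx, 2L * hid, cout, 1L, 1L, sh)
  m <- new.env(parent = emptyenv())
  m$cout <- cout; m$sh_out <- sh
  m$fw <- function(hx) {
    a <- cv1$fw(hx)
    for (b in bns) a <- b$fw(a)
    cv3$fw(f_concat(a, cv2$fw(hx)))
  }
  m$bw <- function(hdy) {
    dcat <- cv3$bw(hdy)
    da <- f_slice(dcat, 1L, hid)
    db <- f_slice(dcat, hid + 1L, hid)
    for (b in rev(bns)) da <- b$bw(da)
    f_add(cv1$bw(da), cv2$bw(db))
  }
  m
}

spp_block <- function(ctx, cin, cout, sh, kernels = c(5L, 9L, 13L)) {
  hid <- cin %/% 2L
  cv1 <- base_conv(ctx, cin, hid, 1L, 1L, sh)
  cv2 <- base_conv(ctx, hid * (length(kernels) + 1L), cout, 1L, 1L, sh)
  m <- new.env(parent = emptyenv())
  m$cout <- cout; m$sh_out <- sh
  m$fw <- function(hx) {
    a <- cv1$fw(hx)
    y <- a
    m$ioff <- numeric(length(kernels))
    for (i in seq_along(kernels)) {
      r <- f_maxpool_fw(a, kernels[i])
      m$ioff[i] <- r$ioff
      y <- f_concat(y, r$y)
    }
    cv2$fw(y)
  }
  m$bw <- function(hdy) {
    dcat <- cv2$bw(hdy)
    da <- f_slice(dcat, 1L, hid)
    for (i in seq_along(kernels)) {
      dpi <- f_slice(dcat, i * hid + 1L, hid)
      da <- f_add(da, f_maxpool_bw(dpi, m$ioff[i]))
    }
    cv1$bw(da)
  }
  m
}
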