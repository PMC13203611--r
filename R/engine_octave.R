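# Dual-frequency (octave) modules.
#
# A dual-frequency feature is list(h = <handle|NULL>, l = <handle|NULL>):
# the high-frequency part at full resolution and the low-frequency part at
# half resolution, channel counts split as round(alpha * C) low / rest
# high. An octave convolution runs up to four weight paths (H->H, H->L,
# L->H, L->L); inter-frequency paths change resolution with parameter-free
# x2 average pooling (before the conv) and nearest-neighbour upsampling
# (after the conv), so every path convolves at the resolution of its output
# group. The four paths together hold exactly as many weights as the plain
# convolution they replace, for every alpha.

# octave convolution; bnmode "group" = one fused norm+SiLU per summed
# output group (drop-in replacement for conv+norm+act), "path" = one norm
# per path before summation with SiLU after the sum (cross-fusion modules)
o_conv <- function(ctx, cin, cout, k, stride, sh_in, a_in, a_out,
                   bnmode = "group", inter = TRUE) {
  cil <- low_channels(cin, a_in); cih <- cin - cil
  col <- low_channels(cout, a_out); coh <- cout - col
  if ((cil == 0L || cih == 0L) && a_in > 0 && a_in < 1)
    stop("channel count too small for alpha split: C=", cin)
  sh_out <- sh_in %/% stride
  sh_lo_in <- sh_in %/% 2L
  sh_lo_out <- sh_out %/% 2L
  pathnorm <- identical(bnmode, "path")
  hh <- if (cih > 0L && coh > 0L) m_conv(ctx, cih, coh, k, stride, sh_in)
  hl <- if (inter && cih > 0L && col > 0L)
    m_conv(ctx, cih, col, k, stride, sh_lo_in)
  lh <- if (inter && cil > 0L && coh > 0L)
    m_conv(ctx, cil, coh, k, stride, sh_lo_in)
  ll <- if (cil > 0L && col > 0L) m_conv(ctx, cil, col, k, stride, sh_lo_in)
  if (pathnorm) {
    n_hh <- if (!is.null(hh)) m_norm(ctx, coh, sh_out)
    n_hl <- if (!is.null(hl)) m_norm(ctx, col, sh_lo_out)
    n_lh <- if (!is.null(lh)) m_norm(ctx, coh, sh_lo_out)
    n_ll <- if (!is.null(ll)) m_norm(ctx, col, sh_lo_out)
    a_h <- if (coh > 0L) m_silu()
    a_l <- if (col > 0L) m_silu()
  } else {
    ns_h <- if (coh > 0L) m_normsilu(ctx, coh, sh_out)
    ns_l <- if (col > 0L) m_normsilu(ctx, col, sh_lo_out)
  }
  m <- new.env(parent = emptyenv())
  m$cout <- cout; m$cout_h <- coh; m$cout_l <- col
  m$cin_h <- cih; m$cin_l <- cil
  m$sh_out <- sh_out
  m$fw <- function(xd) {
    yh <- NULL; yl <- NULL
    if (!is.null(hh)) {
      p <- hh$fw(xd$h); if (pathnorm) p <- n_hh$fw(p)
      yh <- p
    }
    if (!is.null(lh)) {
      p <- lh$fw(xd$l); if (pathnorm) p <- n_lh$fw(p)
      p <- f_upsample2_fw(p)
      yh <- if (is.null(yh)) p else f_add(yh, p)
    }
    if (!is.null(hl)) {
      p <- hl$fw(f_avgpool2_fw(xd$h)); if (pathnorm) p <- n_hl$fw(p)
      yl <- p
    }
    if (!is.null(ll)) {
      p <- ll$fw(xd$l); if (pathnorm) p <- n_ll$fw(p)
      yl <- if (is.null(yl)) p else f_add(yl, p)
    }
    if (pathnorm) {
      if (!is.null(yh)) yh <- a_h$fw(yh)
      if (!is.null(yl)) yl <- a_l$fw(yl)
    } else {
      if (!is.null(yh)) yh <- ns_h$fw(yh)
      if (!is.null(yl)) yl <- ns_l$fw(yl)
    }
    list(h = yh, l = yl)
  }
  m$bw <- function(dyd) {
    dyh <- dyd$h; dyl <- dyd$l
    if (pathnorm) {
      if (!is.null(dyh)) dyh <- a_h$bw(dyh)
      if (!is.null(dyl)) dyl <- a_l$bw(dyl)
    } else {
      if (!is.null(dyh)) dyh <- ns_h$bw(dyh)
      if (!is.null(dyl)) dyl <- ns_l$bw(dyl)
    }
    dxh <- NULL; dxl <- NULL
    if (!is.null(hh)) {
      g <- dyh; if (pathnorm) g <- n_hh$bw(g)
      dxh <- hh$bw(g)
    }
    if (!is.null(lh)) {
      g <- f_upsample2_bw(dyh)
      if (pathnorm) g <- n_lh$bw(g)
      dxl <- lh$bw(g)
    }
    if (!is.null(hl)) {
      g <- dyl; if (pathnorm) g <- n_hl$bw(g)
      g <- f_avgpool2_bw(hl$bw(g))
      dxh <- if (is.null(dxh)) g else f_add(dxh, g)
    }
    if (!is.null(ll)) {
      g <- dyl; if (pathnorm) g <- n_ll$bw(g)
      g <- ll$bw(g)
      dxl <- if (is.null(dxl)) g else f_add(dxl, g)
    }
    list(h = dxh, l = dxl)
  }
  m
}

# depthwise-separable octave unit: per-branch depthwise k x k (with fused
# norm + SiLU) followed by a pointwise octave convolution
o_dw <- function(ctx, cin, cout, k, stride, sh_in, a_in, a_out,
                 inter = TRUE) {
  cil <- low_channels(cin, a_in); cih <- cin - cil
  sh_out <- sh_in %/% stride
  dh <- if (cih > 0L)
    seq_block(m_dwconv(ctx, cih, k, stride, sh_in),
              m_normsilu(ctx, cih, sh_out))
  dl <- if (cil > 0L)
    seq_block(m_dwconv(ctx, cil, k, stride, sh_in %/% 2L),
              m_normsilu(ctx, cil, sh_out %/% 2L))
  pw <- o_conv(ctx, cin, cout, 1L, 1L, sh_out, a_in, a_out, "group",
               inter = inter)
  m <- new.env(parent = emptyenv())
  m$cout <- cout; m$cout_h <- pw$cout_h; m$cout_l <- pw$cout_l
  m$sh_out <- sh_out
  m$fw <- function(xd) {
    pw$fw(list(h = if (!is.null(dh)) dh$fw(xd$h),
               l = if (!is.null(dl)) dl$fw(xd$l)))
  }
  m$bw <- function(dyd) {
    d <- pw$bw(dyd)
    list(h = if (!is.null(dh)) dh$bw(d$h),
         l = if (!is.null(dl)) dl$bw(d$l))
  }
  m
}

o_unit <- function(ctx, cin, cout, k, stride, sh_in, a, depthwise = FALSE,
                   a_out = a, inter = TRUE) {
  if (depthwise && k > 1L)
    o_dw(ctx, cin, cout, k, stride, sh_in, a, a_out, inter = inter)
  else o_conv(ctx, cin, cout, k, stride, sh_in, a, a_out, "group",
              inter = inter)
}

dual_add <- function(a, b) {
  list(h = if (is.null(a$h)) b$h else if (is.null(b$h)) a$h
           else f_add(a$h, b$h),
       l = if (is.null(a$l)) b$l else if (is.null(b$l)) a$l
           else f_add(a$l, b$l))
}

dual_concat <- function(a, b) {
  list(h = if (is.null(a$h)) b$h else if (is.null(b$h)) a$h
           else f_concat(a$h, b$h),
       l = if (is.null(a$l)) b$l else if (is.null(b$l)) a$l
           else f_concat(a$l, b$l))
}

dual_slice <- function(x, from_h, n_h, from_l, n_l) {
  list(h = if (n_h > 0L) f_slice(x$h, from_h, n_h),
       l = if (n_l > 0L) f_slice(x$l, from_l, n_l))
}

o_bottleneck <- function(ctx, c, sh, a, shortcut = TRUE, depthwise = FALSE,
                         inter = TRUE) {
  c1 <- o_unit(ctx, c, c, 1L, 1L, sh, a, inter = inter)
  c2 <- o_unit(ctx, c, c, 3L, 1L, sh, a, depthwise, inter = inter)
  m <- new.env(parent = emptyenv())
  m$cout <- c; m$sh_out <- sh
  m$fw <- function(xd) {
    y <- c2$fw(c1$fw(xd))
    if (shortcut) dual_add(y, xd) else y
  }
  m$bw <- function(dyd) {
    dx <- c1$bw(c2$bw(dyd))
    if (shortcut) dual_add(dx, dyd) else dx
  }
  m
}

o_csp <- function(ctx, cin, cout, n, sh, a, shortcut = TRUE,
                  depthwise = FALSE, inter = TRUE) {
  hid <- cout %/% 2L
  hid_l <- low_channels(hid, a); hid_h <- hid - hid_l
  cv1 <- o_unit(ctx, cin, hid, 1L, 1L, sh, a, inter = inter)
  cv2 <- o_unit(ctx, cin, hid, 1L, 1L, sh, a, inter = inter)
  bns <- lapply(seq_len(n), function(i)
    o_bottleneck(ctx, hid, sh, a, shortcut, depthwise, inter = inter))
  cv3 <- o_unit(ctx, 2L * hid, cout, 1L, 1L, sh, a, inter = inter)
  m <- new.env(parent = emptyenv())
  m$cout <- cout; m$cout_h <- cv3$cout_h; m$cout_l <- cv3$cout_l
  m$sh_out <- sh
  m$fw <- function(xd) {
    av <- cv1$fw(xd)
    for (b in bns) av <- b$fw(av)
    cv3$fw(dual_concat(av, cv2$fw(xd)))
  }
  m$bw <- function(dyd) {
    dcat <- cv3$bw(dyd)
    da <- dual_slice(dcat, 1L, hid_h, 1L, hid_l)
    db <- dual_slice(dcat, hid_h + 1L, hid_h, hid_l + 1L, hid_l)
    for (b in rev(bns)) da <- b$bw(da)
    dual_add(cv1$bw(da), cv2$bw(db))
  }
  m
}

o_spp <- function(ctx, cin, cout, sh, a, kernels = c(5L, 9L, 13L),
                  inter = TRUE) {
  hid <- cin %/% 2L
  hid_l <- low_channels(hid, a); hid_h <- hid - hid_l
  cv1 <- o_unit(ctx, cin, hid, 1L, 1L, sh, a, inter = inter)
  cv2 <- o_unit(ctx, hid * (length(kernels) + 1L), cout, 1L, 1L, sh, a,
                inter = inter)
  m <- new.env(parent = emptyenv())
  m$cout <- cout; m$sh_out <- sh
  pool_cat <- function(x, slot) {
    y <- x
    offs <- numeric(length(kernels))
    for (i in seq_along(kernels)) {
      r <- f_maxpool_fw(x, kernels[i])
      offs[i] <- r$ioff
      y <- f_concat(y, r$y)
    }
    m[[slot]] <- offs
    y
  }
  unpool <- function(dcat, nhid, offs) {
    dx <- f_slice(dcat, 1L, nhid)
    for (i in seq_along(kernels)) {
      dpi <- f_slice(dcat, i * nhid + 1L, nhid)
      dx <- f_add(dx, f_maxpool_bw(dpi, offs[i]))
    }
    dx
  }
  m$fw <- function(xd) {
    av <- cv1$fw(xd)
    yh <- if (!is.null(av$h)) pool_cat(av$h, "ioff_h")
    yl <- if (!is.null(av$l)) pool_cat(av$l, "ioff_l")
    cv2$fw(list(h = yh, l = yl))
  }
  m$bw <- function(dyd) {
    dcat <- cv2$bw(dyd)
    dh <- if (!is.null(dcat$h)) unpool(dcat$h, hid_h, m$ioff_h)
    dl <- if (!is.null(dcat$l)) unpool(dcat$l, hid_l, m$ioff_l)
    cv1$bw(list(h = dh, l = dl))
  }
  m
}

# single-stream -> dual split: trailing round(alpha*C) channels are pooled
# to half resolution as the low-frequency group
split_stream <- function(c, a) {
  cl <- low_channels(c, a); ch <- c - cl
  m <- new.env(parent = emptyenv())
  m$cout_h <- ch; m$cout_l <- cl
  m$fw <- function(hx) {
    if (cl == 0L) return(list(h = hx, l = NULL))
    list(h = f_slice(hx, 1L, ch),
         l = f_avgpool2_fw(f_slice(hx, ch + 1L, cl)))
  }
  m$bw <- function(dyd) {
    if (cl == 0L) return(dyd$h)
    f_concat(dyd$h, f_avgpool2_bw(dyd$l))
  }
  m
}

# dual -> single merge by channel concatenation of high and upsampled low
merge_concat <- function() {
  m <- new.env(parent = emptyenv())
  m$fw <- function(xd) {
    if (is.null(xd$l)) { m$ch <- NULL; return(xd$h) }
    m$ch <- h_dim(xd$h)[3]
    m$cl <- h_dim(xd$l)[3]
    f_concat(xd$h, f_upsample2_fw(xd$l))
  }
  m$bw <- function(hdy) {
    if (is.null(m$ch)) return(list(h = hdy, l = NULL))
    list(h = f_slice(hdy, 1L, m$ch),
         l = f_upsample2_bw(f_slice(hdy, m$ch + 1L, m$cl)))
  }
  m
}

# cross-fusion module: full octave exchange with per-path normalisation;
# kernel k; a_out = 0 merges the two streams into a single high output
cross_fusion_block <- function(ctx, c, k, sh, a_in, a_out,
                               depthwise = FALSE) {
  if (depthwise && k > 1L) {
    cil <- low_channels(c, a_in); cih <- c - cil
    dh <- if (cih > 0L)
      seq_block(m_dwconv(ctx, cih, k, 1L, sh),
                m_normsilu(ctx, cih, sh))
    dl <- if (cil > 0L)
      seq_block(m_dwconv(ctx, cil, k, 1L, sh %/% 2L),
                m_normsilu(ctx, cil, sh %/% 2L))
    pw <- o_conv(ctx, c, c, 1L, 1L, sh, a_in, a_out, "path")
    m <- new.env(parent = emptyenv())
    m$cout <- c; m$cout_h <- pw$cout_h; m$cout_l <- pw$cout_l
    m$sh_out <- sh
    m$fw <- function(xd)
      pw$fw(list(h = if (!is.null(dh)) dh$fw(xd$h),
                 l = if (!is.null(dl)) dl$fw(xd$l)))
    m$bw <- function(dyd) {
      d <- pw$bw(dyd)
      list(h = if (!is.null(dh)) dh$bw(d$h),
           l = if (!is.null(dl)) dl$bw(d$l))
    }
    m
  } else {
    o_conv(ctx, c, c, k, 1L, sh, a_in, a_out, "path")
  }
}
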