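# Detector graph builder: backbone (baseline / dual-stream), neck
# (PANet-style baseline / global-fusion-feedback), decoupled head.

build_backbone <- function(ctx, cfg, sh) {
  w <- cfg_widths(cfg); dep <- cfg_depths(cfg)
  dw <- cfg$use_depthwise; a <- cfg$alpha
  st <- w$stages  # stage output widths
  b <- new.env(parent = emptyenv())
  b$stem <- focus_stem(ctx, 3L, w$stem, sh)
  sh2 <- sh %/% 2L; sh4 <- sh %/% 4L; sh8 <- sh %/% 8L
  sh16 <- sh %/% 16L; sh32 <- sh %/% 32L

  if (cfg$backbone == "baseline") {
    b$d2 <- seq_block(conv_unit(ctx, w$stem, st[1], 3L, 2L, sh2, dw),
                      csp_layer(ctx, st[1], st[1], dep[1], sh4, TRUE, dw))
    b$d3 <- seq_block(conv_unit(ctx, st[1], st[2], 3L, 2L, sh4, dw),
                      csp_layer(ctx, st[2], st[2], dep[2], sh8, TRUE, dw))
    b$d4 <- seq_block(conv_unit(ctx, st[2], st[3], 3L, 2L, sh8, dw),
                      csp_layer(ctx, st[3], st[3], dep[3], sh16, TRUE, dw))
    b$d5 <- seq_block(conv_unit(ctx, st[3], st[4], 3L, 2L, sh16, dw),
                      spp_block(ctx, st[4], st[4], sh32),
                      csp_layer(ctx, st[4], st[4], dep[4], sh32, FALSE, dw))
    b$fw <- function(hx) {
      s <- b$stem$fw(hx)
      c2 <- b$d2$fw(s)
      c3 <- b$d3$fw(c2)
      c4 <- b$d4$fw(c3)
      c5 <- b$d5$fw(c4)
      list(c3 = c3, c4 = c4, c5 = c5)
    }
    b$bw <- function(d) {
      dc4 <- f_add(b$d5$bw(d$c5), d$c4)
      dc3 <- f_add(b$d4$bw(dc4), d$c3)
      b$stem$bw(b$d2$bw(b$d3$bw(dc3)))
      invisible(NULL)
    }
    return(b)
  }

  fus <- cfg$backbone == "dsf"
  os <- function(cin, cout, n, sh_dn_in, sh_st, a_out_cf, kcf, has_spp) {
    # one dual stage: stride-2 octave downsample + octave CSP (+ the
    # spatial-pyramid bottleneck at the deepest stage) + cross-fusion
    blocks <- list(o_unit(ctx, cin, cout, 3L, 2L, sh_dn_in, a, dw,
                          inter = fus))
    if (has_spp)
      blocks <- c(blocks, list(o_spp(ctx, cout, cout, sh_st, a, inter = fus)))
    blocks <- c(blocks, list(o_csp(ctx, cout, cout, n, sh_st, a,
                                   shortcut = !has_spp, depthwise = dw,
                                   inter = fus)))
    cf <- if (fus) cross_fusion_block(ctx, cout, kcf, sh_st, a, a_out_cf, dw)
    list(blocks = blocks, cf = cf)
  }
  run_stage <- function(stg, xd) {
    for (bl in stg$blocks) xd <- bl$fw(xd)
    if (!is.null(stg$cf)) xd <- stg$cf$fw(xd)
    xd
  }
  back_stage <- function(stg, dyd) {
    if (!is.null(stg$cf)) dyd <- stg$cf$bw(dyd)
    for (bl in rev(stg$blocks)) dyd <- bl$bw(dyd)
    dyd
  }

  b$split1 <- split_stream(w$stem, a)
  b$s2 <- os(w$stem, st[1], dep[1], sh2, sh4, a, 3L, FALSE)
  b$s3 <- os(st[1], st[2], dep[2], sh4, sh8, a, 3L, FALSE)
  b$mrg3 <- merge_concat()
  b$s4 <- os(st[2], st[3], dep[3], sh8, sh16, 0, 3L, FALSE)
  b$split5 <- split_stream(st[3], a)
  b$s5 <- os(st[3], st[4], dep[4], sh16, sh32, 0, 1L, TRUE)
  b$mrg4 <- if (!fus) merge_concat()
  b$mrg5 <- if (!fus) merge_concat()

  b$fw <- function(hx) {
    s <- b$stem$fw(hx)
    xd <- b$split1$fw(s)
    xd <- run_stage(b$s2, xd)
    x3 <- run_stage(b$s3, xd)           # dual (cross-fused, a_out = alpha)
    c3 <- b$mrg3$fw(x3)                 # concat merge for export
    x4 <- run_stage(b$s4, x3)           # a_out = 0 -> single stream
    c4 <- if (fus) x4$h else b$mrg4$fw(x4)
    x5in <- b$split5$fw(c4)             # re-split the merged stream
    x5 <- run_stage(b$s5, x5in)
    c5 <- if (fus) x5$h else b$mrg5$fw(x5)
    list(c3 = c3, c4 = c4, c5 = c5)
  }
  b$bw <- function(d) {
    dx5 <- if (fus) list(h = d$c5, l = NULL) else b$mrg5$bw(d$c5)
    dc4_from5 <- b$split5$bw(back_stage(b$s5, dx5))
    dc4 <- f_add(d$c4, dc4_from5)
    dx4 <- if (fus) list(h = dc4, l = NULL) else b$mrg4$bw(dc4)
    dx3_from4 <- back_stage(b$s4, dx4)
    dx3 <- dual_add(dx3_from4, b$mrg3$bw(d$c3))
    dxd <- back_stage(b$s2, back_stage(b$s3, dx3))
    b$stem$bw(b$split1$bw(dxd))
    invisible(NULL)
  }
  b
}

build_neck_pafpn <- function(ctx, cfg, sh) {
  w <- cfg_widths(cfg); dw <- cfg$use_depthwise
  n <- max(round(3 * cfg$depth), 1)
  sh8 <- sh %/% 8L; sh16 <- sh %/% 16L; sh32 <- sh %/% 32L
  nk <- new.env(parent = emptyenv())
  nk$lat0 <- base_conv(ctx, w$c5, w$c4, 1L, 1L, sh32)
  nk$p4 <- csp_layer(ctx, 2L * w$c4, w$c4, n, sh16, FALSE, dw)
  nk$red1 <- base_conv(ctx, w$c4, w$c3, 1L, 1L, sh16)
  nk$p3 <- csp_layer(ctx, 2L * w$c3, w$c3, n, sh8, FALSE, dw)
  nk$bu2 <- conv_unit(ctx, w$c3, w$c3, 3L, 2L, sh8, dw)
  nk$n3 <- csp_layer(ctx, 2L * w$c3, w$c4, n, sh16, FALSE, dw)
  nk$bu1 <- conv_unit(ctx, w$c4, w$c4, 3L, 2L, sh16, dw)
  nk$n4 <- csp_layer(ctx, 2L * w$c4, w$c5, n, sh32, FALSE, dw)
  nk$out_channels <- c(w$c3, w$c4, w$c5)
  nk$fw <- function(p) {
    f0 <- nk$lat0$fw(p$c5)                         # c4 channels @ s32
    f1 <- nk$p4$fw(f_concat(f_upsample2_fw(f0), p$c4))
    f1r <- nk$red1$fw(f1)                          # c3 channels @ s16
    o3 <- nk$p3$fw(f_concat(f_upsample2_fw(f1r), p$c3))
    o4 <- nk$n3$fw(f_concat(nk$bu2$fw(o3), f1r))
    o5 <- nk$n4$fw(f_concat(nk$bu1$fw(o4), f0))
    list(p3 = o3, p4 = o4, p5 = o5)
  }
  nk$bw <- function(dp) {
    w3 <- w$c3; w4 <- w$c4
    dcat5 <- nk$n4$bw(dp$p5)
    do4 <- f_add(dp$p4, nk$bu1$bw(f_slice(dcat5, 1L, w4)))
    df0 <- f_slice(dcat5, w4 + 1L, w4)
    dcat4 <- nk$n3$bw(do4)
    do3 <- f_add(dp$p3, nk$bu2$bw(f_slice(dcat4, 1L, w3)))
    df1r <- f_slice(dcat4, w3 + 1L, w3)
    dcat3 <- nk$p3$bw(do3)
    dc3 <- f_slice(dcat3, w3 + 1L, w3)
    df1r <- f_add(df1r, f_upsample2_bw(f_slice(dcat3, 1L, w3)))
    dcat2 <- nk$p4$bw(nk$red1$bw(df1r))
    dc4 <- f_slice(dcat2, w4 + 1L, w4)
    df0 <- f_add(df0, f_upsample2_bw(f_slice(dcat2, 1L, w4)))
    dc5 <- nk$lat0$bw(df0)
    list(c3 = dc3, c4 = dc4, c5 = dc5)
  }
  nk
}

build_neck_gff <- function(ctx, cfg, sh, pool_scales = c(1L, 2L, 3L, 6L)) {
  w <- cfg_widths(cfg)
  R <- w$c3
  sh8 <- sh %/% 8L; sh16 <- sh %/% 16L; sh32 <- sh %/% 32L
  cin <- w$c4 + w$c5
  nk <- new.env(parent = emptyenv())
  nk$pool_scales <- pool_scales
  nk$ppm_convs <- lapply(pool_scales, function(s)
    base_conv(ctx, cin, R, 1L, 1L, c(s, s)))
  nk$fuse <- base_conv(ctx, length(pool_scales) * R, R, 1L, 1L, sh16)
  nk$post <- base_conv(ctx, R, R, 1L, 1L, sh8)
  nk$p4c <- base_conv(ctx, R + w$c4, w$c4, 1L, 1L, sh16)
  nk$p5c <- base_conv(ctx, R + w$c5, w$c5, 1L, 1L, sh32)
  nk$out_channels <- c(w$c3, w$c4, w$c5)
  nk$fw <- function(p) {
    ctx45 <- f_concat(p$c4, f_upsample2_fw(p$c5))
    nk$dctx <- h_dim(ctx45)
    br <- vector("list", length(pool_scales))
    for (i in seq_along(pool_scales)) {
      s <- pool_scales[i]
      pooled <- f_adapool_fw(ctx45, s)
      br[[i]] <- f_upto_fw(nk$ppm_convs[[i]]$fw(pooled), sh16[1], sh16[2])
    }
    cat_br <- br[[1]]
    for (i in seq_along(br)[-1]) cat_br <- f_concat(cat_br, br[[i]])
    fused <- nk$fuse$fw(cat_br)
    gf <- f_add(nk$post$fw(f_upsample2_fw(fused)), p$c3)  # GF @ stride 8
    gf16 <- f_avgpool2_fw(gf)
    gf32 <- f_avgpool2_fw(gf16)
    o4 <- nk$p4c$fw(f_concat(gf16, p$c4))
    o5 <- nk$p5c$fw(f_concat(gf32, p$c5))
    list(p3 = gf, p4 = o4, p5 = o5, gf = gf)
  }
  nk$bw <- function(dp) {
    dcat5 <- nk$p5c$bw(dp$p5)
    dgf32 <- f_slice(dcat5, 1L, R)
    dc5_fb <- f_slice(dcat5, R + 1L, w$c5)
    dcat4 <- nk$p4c$bw(dp$p4)
    dgf16 <- f_add(f_slice(dcat4, 1L, R), f_avgpool2_bw(dgf32))
    dc4_fb <- f_slice(dcat4, R + 1L, w$c4)
    dgf <- f_add(dp$p3, f_avgpool2_bw(dgf16))
    dc3 <- dgf                                     # additive combination
    dfused <- f_upsample2_bw(nk$post$bw(dgf))
    dcat_br <- nk$fuse$bw(dfused)
    dctx <- NULL
    for (i in seq_along(pool_scales)) {
      s <- pool_scales[i]
      dbr <- f_upto_bw(f_slice(dcat_br, (i - 1L) * R + 1L, R), s, s)
      dpooled <- nk$ppm_convs[[i]]$bw(dbr)
      g <- f_adapool_bw(dpooled, nk$dctx[1], nk$dctx[2])
      dctx <- if (is.null(dctx)) g else f_add(dctx, g)
    }
    dc4 <- f_add(dc4_fb, f_slice(dctx, 1L, w$c4))
    dc5 <- f_add(dc5_fb, f_upsample2_bw(f_slice(dctx, w$c4 + 1L, w$c5)))
    list(c3 = dc3, c4 = dc4, c5 = dc5)
  }
  nk
}

build_head <- function(ctx, cfg, sh, in_channels) {
  w <- cfg_widths(cfg); dw <- cfg$use_depthwise
  hw <- w$head; ncls <- cfg$num_classes
  shs <- list(sh %/% 8L, sh %/% 16L, sh %/% 32L)
  prior_bias <- log(0.01 / (1 - 0.01))  # objectness/class prior of 1%
  hd <- new.env(parent = emptyenv())
  hd$levels <- lapply(1:3, function(l) {
    lv <- new.env(parent = emptyenv())
    lv$stem <- base_conv(ctx, in_channels[l], hw, 1L, 1L, shs[[l]])
    lv$cls1 <- conv_unit(ctx, hw, hw, 3L, 1L, shs[[l]], dw)
    lv$cls2 <- conv_unit(ctx, hw, hw, 3L, 1L, shs[[l]], dw)
    lv$reg1 <- conv_unit(ctx, hw, hw, 3L, 1L, shs[[l]], dw)
    lv$reg2 <- conv_unit(ctx, hw, hw, 3L, 1L, shs[[l]], dw)
    lv$cls_p <- m_conv(ctx, hw, ncls, 1L, 1L, shs[[l]], bias = TRUE,
                       bias_init = prior_bias)
    lv$reg_p <- m_conv(ctx, hw, 4L, 1L, 1L, shs[[l]], bias = TRUE)
    lv$obj_p <- m_conv(ctx, hw, 1L, 1L, 1L, shs[[l]], bias = TRUE,
                       bias_init = prior_bias)
    lv
  })
  hd$fw <- function(p) {
    feats <- list(p$p3, p$p4, p$p5)
    lapply(1:3, function(l) {
      lv <- hd$levels[[l]]
      s <- lv$stem$fw(feats[[l]])
      cf <- lv$cls2$fw(lv$cls1$fw(s))
      rf <- lv$reg2$fw(lv$reg1$fw(s))
      list(cls = lv$cls_p$fw(cf), reg = lv$reg_p$fw(rf),
           obj = lv$obj_p$fw(rf))
    })
  }
  hd$bw <- function(douts) {
    dp <- lapply(1:3, function(l) {
      lv <- hd$levels[[l]]
      dcf <- lv$cls_p$bw(douts[[l]]$cls)
      drf <- f_add(lv$reg_p$bw(douts[[l]]$reg), lv$obj_p$bw(douts[[l]]$obj))
      ds <- f_add(lv$cls1$bw(lv$cls2$bw(dcf)), lv$reg1$bw(lv$reg2$bw(drf)))
      lv$stem$bw(ds)
    })
    list(p3 = dp[[1]], p4 = dp[[2]], p5 = dp[[3]])
  }
  hd
}

#' Build a detector
#'
#' Instantiates the full detection network (backbone, neck, decoupled head)
#' for a given configuration and input size. The returned object carries
#' the forward/backward passes used by [train_detector()] and [detect()],
#' plus the symbolic layer table used by the profiler. Forward input is an
#' (H, W, 3) array scaled to \[0, 1\]; outputs are per-level lists of
#' class, box-regression and objectness logit arrays.
#'
#' @param cfg a [model_config()].
#' @param input_size integer (height, width), divisible by 32.
#' @param alloc if `FALSE`, no weights are allocated (profiling only).
#' @param seed optional integer seed for weight initialisation.
#' @return an environment of class `sonolite_model`.
#' @export
build_detector <- function(cfg, input_size = c(640L, 640L), alloc = TRUE,
                           seed = NULL) {
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  sh <- as.integer(input_size)
  if (any(sh %% 32L != 0L)) stop("input size must be divisible by 32")
  if (!is.null(seed)) set.seed(seed)
  ctx <- new_net_ctx(alloc = alloc)
  bb <- build_backbone(ctx, cfg, sh)
  n_bb <- length(ctx$rows)
  nk <- if (cfg$neck == "gff") build_neck_gff(ctx, cfg, sh)
        else build_neck_pafpn(ctx, cfg, sh)
  n_nk <- length(ctx$rows)
  hd <- build_head(ctx, cfg, sh, nk$out_channels)
  n_hd <- length(ctx$rows)
  md <- new.env(parent = emptyenv())
  md$cfg <- cfg; md$ctx <- ctx; md$input_size <- sh
  md$sections <- c(backbone = n_bb, neck = n_nk - n_bb, head = n_hd - n_nk)
  md$backbone <- bb; md$neck <- nk; md$head <- hd
  md$strides <- c(8L, 16L, 32L)
  md$forward <- function(x, training = TRUE) {
    ctx$training <- training
    f_reset(0L)
    hx <- f_from_dbl(x, sh[1], sh[2], 3L, 0L)
    pyr <- bb$fw(hx)
    feats <- nk$fw(pyr)
    outs <- hd$fw(feats)
    lapply(outs, function(o) list(cls = f_to_dbl(o$cls),
                                  reg = f_to_dbl(o$reg),
                                  obj = f_to_dbl(o$obj)))
  }
  md$backward <- function(douts) {
    f_reset(1L)
    hd_grads <- lapply(douts, function(o) {
      list(cls = f_from_dbl(o$cls, dim(o$cls)[1], dim(o$cls)[2],
                            dim(o$cls)[3], 1L),
           reg = f_from_dbl(o$reg, dim(o$reg)[1], dim(o$reg)[2],
                            dim(o$reg)[3], 1L),
           obj = f_from_dbl(o$obj, dim(o$obj)[1], dim(o$obj)[2],
                            dim(o$obj)[3], 1L))
    })
    dfeats <- hd$bw(hd_grads)
    dpyr <- nk$bw(dfeats)
    bb$bw(dpyr)
    invisible(NULL)
  }
  class(md) <- "sonolite_model"
  md
}

#' @export
print.sonolite_model <- function(x, ...) {
  p <- count_params(x)
  cat(sprintf("<sonolite_model> %s @ %dx%d, %.3f M parameters\n",
              x$cfg$variant, x$input_size[1], x$input_size[2], p / 1e6))
  invisible(x)
}
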