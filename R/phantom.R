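# Synthetic B-mode ultrasound phantom generator.
#
# Emulates the structure of a free-fluid screening dataset: speckled
# parenchyma with bright curvilinear tissue bands, irregular hypoechoic
# fluid pockets with continuous boundaries (star-convex outlines with
# smoothed random radii), target-free frames, and the physical
# top-to-bottom orientation of B-mode imaging. Echo amplitude is modulated
# by a Rayleigh-distributed multiplicative speckle field smoothed with a
# short-range kernel and log-compressed to 8 bit.

#' Phantom generator configuration
#'
#' @param image_size (H, W) in pixels.
#' @param n_images number of frames.
#' @param p_empty fraction of target-free frames (the source data retain
#'   frames where probe movement lost the fluid; the default 0.15 is a
#'   free choice, see the methods vignette).
#' @param fluid_count_range (min, max) fluid pockets per positive frame.
#' @param contrast parenchyma-to-fluid reflectivity ratio (> 1); the
#'   default 12 renders pockets nearly anechoic after log compression, as
#'   free fluid appears in B-mode imaging.
#' @param speckle_scale Rayleigh scale of the multiplicative speckle.
#' @param sector_mask zero out pixels outside a fan-shaped field of view.
#' @param seed integer; the dataset is a pure function of the
#'   configuration, identical seeds give byte-identical datasets.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = c(320L, 320L), n_images = 16L,
                           p_empty = 0.15, fluid_count_range = c(1L, 3L),
                           contrast = 12, speckle_scale = 0.35,
                           sector_mask = FALSE, seed = 1L) {
  stopifnot(p_empty >= 0, p_empty <= 1, contrast > 1,
            fluid_count_range[1] >= 1L)
  cfg <- list(image_size = as.integer(image_size),
              n_images = as.integer(n_images), p_empty = p_empty,
              fluid_count_range = as.integer(fluid_count_range),
              contrast = contrast, speckle_scale = speckle_scale,
              sector_mask = sector_mask, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# separable box-ish gaussian blur (small sigma) on a matrix
blur_mat <- function(m, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  # pad by replication, filter rows then columns
  pad <- function(x, n) x[c(rep(1, n), seq_len(length(x)), rep(length(x), n))]
  m2 <- apply(m, 2, function(col) stats::filter(pad(col, r), k)[r + seq_len(H)])
  m3 <- t(apply(m2, 1, function(row) stats::filter(pad(row, r), k)[r + seq_len(W)]))
  m3
}

# smooth periodic random radius profile for a star-convex outline
star_radii <- function(n_pts, mean_r, irregularity = 0.35, n_harm = 4L) {
  th <- seq(0, 2 * pi, length.out = n_pts + 1L)[-(n_pts + 1L)]
  r <- rep(1, n_pts)
  for (h in seq_len(n_harm)) {
    r <- r + irregularity / h * (cos(h * th) * rnorm(1) + sin(h * th) * rnorm(1))
  }
  mean_r * pmax(r, 0.3)
}

# rasterise a polygon (point-in-polygon by even-odd rule, vectorised rows)
poly_mask <- function(H, W, px, py) {
  mask <- matrix(FALSE, H, W)
  y0 <- max(1L, floor(min(py))); y1 <- min(H, ceiling(max(py)))
  n <- length(px)
  for (y in y0:y1) {
    xs <- c()
    j <- n
    for (i in seq_len(n)) {
      if ((py[i] > y) != (py[j] > y)) {
        xs <- c(xs, px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i]))
      }
      j <- i
    }
    xs <- sort(xs)
    if (length(xs) >= 2) {
      for (k in seq(1, length(xs) - 1, by = 2)) {
        x0 <- max(1L, ceiling(xs[k])); x1 <- min(W, floor(xs[k + 1]))
        if (x0 <= x1) mask[y, x0:x1] <- TRUE
      }
    }
  }
  mask
}

# one frame; returns list(image = HxW matrix in 0..255, boxes, is_empty)
render_phantom <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  # parenchyma reflectivity: smooth positive field with depth attenuation
  base <- matrix(rnorm(ceiling(H / 8) * ceiling(W / 8)), ceiling(H / 8))
  base <- blur_mat(base, 1.2)
  refl <- 0.75 + 0.2 * (base[ceiling(seq_len(H) / 8), ceiling(seq_len(W) / 8)])
  depth <- matrix(rep(seq(1, 0.7, length.out = H), W), H)
  refl <- pmax(refl * depth, 0.15)
  # bright curvilinear parenchyma bands
  n_band <- sample(2:4, 1)
  xs <- seq_len(W)
  for (b in seq_len(n_band)) {
    y0 <- runif(1, 0.15 * H, 0.9 * H)
    amp <- runif(1, 0.05, 0.18) * H
    ph <- runif(1, 0, 2 * pi)
    per <- runif(1, 0.8, 2.5) * W
    yc <- y0 + amp * sin(2 * pi * xs / per + ph)
    wd <- runif(1, 1.5, 3.5)
    gain <- runif(1, 0.35, 0.7)
    for (x in xs) {
      ys <- round(yc[x] + (-6:6))
      ok <- ys >= 1 & ys <= H
      refl[ys[ok], x] <- refl[ys[ok], x] +
        gain * exp(-((-6:6)[ok])^2 / (2 * wd^2))
    }
  }
  # hypoechoic fluid pockets
  is_empty <- runif(1) < cfg$p_empty
  boxes <- matrix(numeric(0), 0, 4)
  fluid_mask <- matrix(0, H, W)
  if (!is_empty) {
    n_fluid <- sample(seq(cfg$fluid_count_range[1],
                          cfg$fluid_count_range[2]), 1)
    placed <- 0L
    attempts <- 0L
    while (placed < n_fluid) {
      attempts <- attempts + 1L
      if (attempts > 100L) {
        if (placed > 0L) break
        stop("could not place fluid pocket inside image bounds")
      }
      mean_r <- runif(1, 0.06, 0.16) * min(H, W)
      cx <- runif(1, mean_r * 1.8, W - mean_r * 1.8)
      cy <- runif(1, max(mean_r * 1.8, 0.2 * H), H - mean_r * 1.8)
      rr <- star_radii(48L, mean_r)
      th <- seq(0, 2 * pi, length.out = 49L)[-49L]
      px <- cx + rr * cos(th); py <- cy + rr * sin(th)
      if (min(px) < 2 || max(px) > W - 1 || min(py) < 2 || max(py) > H - 1)
        next
      mk <- poly_mask(H, W, px, py)
      if (!any(mk)) next
      fluid_mask[mk] <- 1
      cols <- range(which(colSums(mk) > 0)); rows <- range(which(rowSums(mk) > 0))
      boxes <- rbind(boxes, c(cols[1] - 1, rows[1] - 1, cols[2], rows[2]))
      placed <- placed + 1L
    }
  }
  # soften pocket boundary, keep interiors strongly hypoechoic
  if (any(fluid_mask > 0)) {
    soft <- blur_mat(fluid_mask, 1.5)
    refl <- refl * (1 - soft * (1 - 1 / cfg$contrast))
    # slight posterior enhancement under fluid (acoustic transmission)
    cumf <- apply(fluid_mask, 2, cumsum)
    refl <- refl * (1 + 0.08 * (cumf > 0 & fluid_mask == 0))
  }
  # multiplicative Rayleigh speckle, short-range smoothed
  ray <- matrix(sqrt(rexp(H * W, rate = 1 / (2 * cfg$speckle_scale^2))), H)
  ray <- blur_mat(ray, 0.8)
  env <- refl * ray
  img <- log1p(60 * env) / log1p(60)
  if (cfg$sector_mask) {
    apex_x <- W / 2
    ang <- atan2(matrix(rep(seq_len(W) - apex_x, each = H), H),
                 matrix(rep(seq_len(H), W), H))
    img[abs(ang) > pi / 4 & abs(ang) < pi] <- img[abs(ang) > pi / 4 &
                                                  abs(ang) < pi] * 0
    img[matrix(rep(seq_len(H), W), H) < 0.03 * H] <- 0
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = round(img * 255), boxes = boxes,
       is_empty = nrow(boxes) == 0L)
}

#' Generate a phantom dataset
#'
#' @param cfg a [phantom_config()].
#' @return list of annotated frames, each `list(image, boxes, is_empty)`
#'   with `image` an (H, W) matrix of 8-bit intensities and `boxes` an
#'   n x 4 matrix of (x1, y1, x2, y2) pixel corners (half-open); class
#'   `phantom_dataset`.
#' @export
#' @examples
#' ds <- generate_phantoms(phantom_config(n_images = 2, seed = 7))
#' length(ds)
generate_phantoms <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  out <- vector("list", cfg$n_images)
  for (i in seq_len(cfg$n_images)) {
    set.seed(cfg$seed * 10007L + i)
    out[[i]] <- render_phantom(cfg)
    out[[i]]$id <- i
  }
  attr(out, "config") <- cfg
  class(out) <- "phantom_dataset"
  out
}

#' @export
print.phantom_dataset <- function(x, ...) {
  n_emp <- sum(vapply(x, function(s) s$is_empty, logical(1)))
  cat(sprintf("<phantom_dataset> %d frames (%d target-free), %dx%d\n",
              length(x), n_emp, nrow(x[[1]]$image), ncol(x[[1]]$image)))
  invisible(x)
}

# convert a phantom frame to model input (H, W, 3) in [0, 1]
frame_to_input <- function(img) {
  x <- img / 255
  array(rep(x, 3L), c(nrow(img), ncol(img), 3L))
}
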