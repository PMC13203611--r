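# Training-time augmentation: horizontal flip, Mosaic, MixUp.
#
# B-mode frames have a fixed physical orientation (probe at the top,
# shadows/artefacts below), so flips are horizontal only; the pipeline
# deliberately exposes no vertical flip.

#' Horizontal flip of an annotated frame
#'
#' Mirrors the image about the vertical axis; a box (x1, y1, x2, y2)
#' becomes (W - x2, y1, W - x1, y2). An involution:
#' `hflip(hflip(s))` equals `s`.
#'
#' @param sample `list(image, boxes, is_empty)`.
#' @return the flipped sample.
#' @export
hflip <- function(sample) {
  W <- ncol(sample$image)
  img <- sample$image[, rev(seq_len(W)), drop = FALSE]
  b <- sample$boxes
  if (nrow(b) > 0) {
    b <- cbind(W - b[, 3], b[, 2], W - b[, 1], b[, 4])
  }
  list(image = img, boxes = b, is_empty = sample$is_empty)
}

# nearest-neighbour resize of a matrix to (H, W)
resize_mat <- function(m, H, W) {
  iy <- pmin(nrow(m), floor((seq_len(H) - 0.5) * nrow(m) / H) + 1L)
  ix <- pmin(ncol(m), floor((seq_len(W) - 0.5) * ncol(m) / W) + 1L)
  m[iy, ix, drop = FALSE]
}

#' Mosaic augmentation
#'
#' Tiles four samples around a jittered centre point of a double-size
#' canvas, then crops the central `out_size` window. Boxes are scaled,
#' shifted and clipped; boxes whose clipped width or height falls below
#' `min_box` pixels are dropped.
#'
#' @param samples list of exactly 4 annotated frames.
#' @param out_size (H, W) of the output frame.
#' @param jitter centre jitter range as a fraction of `out_size`.
#' @param centre optional fixed centre (cy, cx) on the 2x canvas
#'   (overrides the random draw; used for deterministic layouts).
#' @param min_box minimum retained box side after clipping, pixels.
#' @return an annotated frame.
#' @export
mosaic <- function(samples, out_size, jitter = 0.25, centre = NULL,
                   min_box = 2) {
  stopifnot(length(samples) == 4L)
  H <- out_size[1]; W <- out_size[2]
  CH <- 2L * H; CW <- 2L * W
  if (is.null(centre)) {
    cy <- round(H + runif(1, -jitter, jitter) * H)
    cx <- round(W + runif(1, -jitter, jitter) * W)
  } else { cy <- centre[1]; cx <- centre[2] }
  canvas <- matrix(114, CH, CW)
  all_boxes <- matrix(numeric(0), 0, 4)
  # quadrant extents on the canvas: (top-left, top-right, bottom-left,
  # bottom-right) around the centre point
  ext <- list(c(1, cy, 1, cx), c(1, cy, cx + 1, CW),
              c(cy + 1, CH, 1, cx), c(cy + 1, CH, cx + 1, CW))
  for (q in 1:4) {
    e <- ext[[q]]
    th <- e[2] - e[1] + 1L; tw <- e[4] - e[3] + 1L
    if (th < 2 || tw < 2) next
    s <- samples[[q]]
    sy <- th / nrow(s$image); sx <- tw / ncol(s$image)
    canvas[e[1]:e[2], e[3]:e[4]] <- resize_mat(s$image, th, tw)
    if (nrow(s$boxes) > 0) {
      b <- s$boxes
      b <- cbind(b[, 1] * sx + e[3] - 1, b[, 2] * sy + e[1] - 1,
                 b[, 3] * sx + e[3] - 1, b[, 4] * sy + e[1] - 1)
      all_boxes <- rbind(all_boxes, b)
    }
  }
  # crop the central window
  y0 <- cy - H %/% 2L; x0 <- cx - W %/% 2L
  y0 <- min(max(y0, 0L), CH - H); x0 <- min(max(x0, 0L), CW - W)
  img <- canvas[y0 + seq_len(H), x0 + seq_len(W)]
  if (nrow(all_boxes) > 0) {
    b <- all_boxes
    b[, c(1, 3)] <- b[, c(1, 3)] - x0
    b[, c(2, 4)] <- b[, c(2, 4)] - y0
    b <- clip_boxes(b, W, H)
    keep <- (b[, 3] - b[, 1]) >= min_box & (b[, 4] - b[, 2]) >= min_box
    b <- b[keep, , drop = FALSE]
  } else b <- all_boxes
  list(image = img, boxes = b, is_empty = nrow(b) == 0L)
}

#' MixUp augmentation
#'
#' Pixel-wise convex combination r a + (1 - r) b of two equally
#' sized frames; the annotation is the union of both box sets.
#'
#' @param a,b annotated frames of equal size.
#' @param r mixing ratio in \[0, 1\].
#' @return an annotated frame.
#' @export
mixup <- function(a, b, r = 0.5) {
  if (!all(dim(a$image) == dim(b$image)))
    stop("mixup requires equally sized frames")
  img <- r * a$image + (1 - r) * b$image
  boxes <- rbind(a$boxes, b$boxes)
  list(image = img, boxes = boxes, is_empty = nrow(boxes) == 0L)
}
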