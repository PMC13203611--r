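# Box utilities: intersection-over-union and greedy NMS.
# Boxes are (x1, y1, x2, y2) in pixels, half-open, origin top-left.

#' Intersection over union of two sets of boxes
#'
#' @param a,b numeric matrices with columns x1, y1, x2, y2.
#' @return an `nrow(a)` x `nrow(b)` matrix of IoU values in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  n <- nrow(a); m <- nrow(b)
  ix1 <- pmax(matrix(a[, 1], n, m), matrix(b[, 1], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2], n, m), matrix(b[, 2], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3], n, m), matrix(b[, 3], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4], n, m), matrix(b[, 4], n, m, byrow = TRUE))
  iw <- pmax(0, ix2 - ix1); ih <- pmax(0, iy2 - iy1)
  inter <- iw * ih
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- matrix(aa, n, m) + matrix(ab, n, m, byrow = TRUE) - inter
  out <- inter / pmax(un, 1e-12)
  out[un <= 0] <- 0
  out
}

#' Greedy non-maximum suppression
#'
#' Detections are sorted by descending score (ties broken by original
#' index); a detection is kept when its IoU with every already-kept
#' detection is at most `iou_thresh`. Class-agnostic (single-category
#' task).
#'
#' @param boxes matrix with columns x1, y1, x2, y2.
#' @param scores numeric vector.
#' @param iou_thresh IoU above which a lower-scored box is suppressed.
#' @return integer indices of the kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_thresh = 0.65) {
  boxes <- matrix(boxes, ncol = 4)
  if (nrow(boxes) == 0L) return(integer(0))
  ord <- order(-scores, seq_along(scores))
  keep <- integer(0)
  while (length(ord) > 0L) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1]
    iou <- box_iou(boxes[i, , drop = FALSE], boxes[rest, , drop = FALSE])
    ord <- rest[iou[1, ] <= iou_thresh]
  }
  keep
}

# clip boxes to image bounds
clip_boxes <- function(b, width, height) {
  b[, 1] <- pmin(pmax(b[, 1], 0), width)
  b[, 3] <- pmin(pmax(b[, 3], 0), width)
  b[, 2] <- pmin(pmax(b[, 2], 0), height)
  b[, 4] <- pmin(pmax(b[, 4], 0), height)
  b
}
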