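# Anchor-free head operations: grid construction, box decoding, SimOTA
# dynamic label assignment and the composite training loss.

# flatten head outputs to per-cell matrices. Head output arrays are
# (H_l, W_l, C); cells are enumerated level by level, within a level in
# column-major order of the (row, col) grid. Returns:
#   reg: n x 4 raw regression (dx, dy, dw, dh); obj, cls: logits;
#   cx0, cy0: cell indices (0-based col j, row i); stride per cell.
flatten_head <- function(outs, strides = c(8L, 16L, 32L)) {
  regs <- list(); objs <- list(); clss <- list()
  jj <- list(); ii <- list(); ss <- list()
  for (l in seq_along(outs)) {
    o <- outs[[l]]
    d <- dim(o$reg)          # (H, W, 4)
    n <- d[1] * d[2]
    regs[[l]] <- matrix(o$reg, n, 4)
    objs[[l]] <- as.numeric(o$obj)
    clss[[l]] <- matrix(o$cls, n, dim(o$cls)[3])
    ii[[l]] <- rep(seq_len(d[1]) - 1L, times = d[2])   # row index i
    jj[[l]] <- rep(seq_len(d[2]) - 1L, each = d[1])    # col index j
    ss[[l]] <- rep(strides[l], n)
  }
  list(reg = do.call(rbind, regs), obj = unlist(objs),
       cls = do.call(rbind, clss),
       i = unlist(ii), j = unlist(jj), stride = unlist(ss),
       level_sizes = vapply(outs, function(o) prod(dim(o$obj)[1:2]),
                            numeric(1)))
}

# decode flattened outputs to boxes (n x 4 corner form) without filtering
decode_cells <- function(fl) {
  s <- fl$stride
  cx <- (fl$j + fl$reg[, 1]) * s
  cy <- (fl$i + fl$reg[, 2]) * s
  w <- exp(fl$reg[, 3]) * s
  h <- exp(fl$reg[, 4]) * s
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

#' Decode head outputs into a detection set
#'
#' Anchor-free decoding: for grid cell (i, j) at stride s the box centre is
#' ((j + dx) s, (i + dy) s) and the box size is (exp(dw) s, exp(dh) s);
#' the confidence is sigmoid(objectness) x sigmoid(class logit).
#'
#' @param outs per-level head outputs (as returned by a model forward).
#' @param strides level strides.
#' @param score_thresh minimum confidence to keep.
#' @param image_size optional (H, W) to clip boxes.
#' @return data.frame with x1, y1, x2, y2, score, label.
#' @export
decode_detections <- function(outs, strides = c(8L, 16L, 32L),
                              score_thresh = 0.001, image_size = NULL) {
  fl <- flatten_head(outs, strides)
  if (any(!is.finite(fl$reg)) || any(!is.finite(fl$obj)))
    stop("non-finite logits in head output")
  boxes <- decode_cells(fl)
  score <- sigmoid(fl$obj) * sigmoid(fl$cls[, 1])
  keep <- which(score >= score_thresh)
  boxes <- boxes[keep, , drop = FALSE]
  if (!is.null(image_size))
    boxes <- clip_boxes(boxes, image_size[2], image_size[1])
  data.frame(x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3],
             y2 = boxes[, 4], score = score[keep],
             label = rep(1L, length(keep)))
}

# binary cross-entropy from a logit, elementwise
bce_logit <- function(logit, target) {
  # log(1 + exp(-|x|)) formulation for stability
  pmax(logit, 0) - logit * target + log1p(exp(-abs(logit)))
}

#' SimOTA dynamic label assignment
#'
#' For each ground-truth box, candidate predictions are grid cells whose
#' centres lie inside the box or within `radius` strides of the box
#' centre. The matching cost is `w_cls * Lcls + w_reg * Lreg` with
#' Lcls the binary cross-entropy of the joint confidence against the class
#' target and Lreg = -log(IoU); cells outside both prior regions carry a
#' large additive penalty. Each ground truth takes its `k` lowest-cost
#' candidates, with k = max(1, floor(sum of its top-10 candidate IoUs));
#' a cell claimed by several ground truths keeps its lowest-cost match.
#'
#' @param fl flattened head outputs (internal form) or per-level outputs.
#' @param gts ground-truth boxes, matrix with columns x1, y1, x2, y2.
#' @param w_cls,w_reg cost weights (defaults 1 and 3).
#' @param radius centre-prior radius in strides.
#' @return list: `pos` (cell indices), `gt_of` (matched gt per positive),
#'   `iou` (IoU of each positive with its gt), `dynamic_k`, `cost`
#'   (gt x candidate cost matrix), `cand` (candidate cell indices).
#' @export
simota_assign <- function(fl, gts, w_cls = 1, w_reg = 3, radius = 2.5) {
  if (!is.null(fl$reg) && is.null(fl$stride)) stop("expected flattened head")
  if (is.null(fl$stride)) fl <- flatten_head(fl)
  gts <- matrix(gts, ncol = 4)
  ng <- nrow(gts)
  if (ng == 0L) stop("simota_assign requires at least one ground truth")
  s <- fl$stride
  ccx <- (fl$j + 0.5) * s         # cell centres
  ccy <- (fl$i + 0.5) * s
  n <- length(s)
  in_box <- matrix(FALSE, ng, n); in_ctr <- matrix(FALSE, ng, n)
  for (g in seq_len(ng)) {
    in_box[g, ] <- ccx >= gts[g, 1] & ccx < gts[g, 3] &
                   ccy >= gts[g, 2] & ccy < gts[g, 4]
    gcx <- (gts[g, 1] + gts[g, 3]) / 2; gcy <- (gts[g, 2] + gts[g, 4]) / 2
    in_ctr[g, ] <- abs(ccx - gcx) <= radius * s & abs(ccy - gcy) <= radius * s
  }
  cand <- which(colSums(in_box | in_ctr) > 0)
  fallback <- FALSE
  if (length(cand) == 0L) {       # no cell in any prior: fall back to all
    cand <- seq_len(n)
    fallback <- TRUE
  }
  boxes <- decode_cells(fl)[cand, , drop = FALSE]
  iou <- box_iou(gts, boxes)                       # ng x ncand
  joint <- sigmoid(fl$obj[cand]) * sigmoid(fl$cls[cand, 1])
  l_cls <- matrix(rep(-log(pmax(joint, 1e-9)), each = ng), ng)
  l_reg <- -log(pmax(iou, 1e-9))
  both <- (in_box & in_ctr)[, cand, drop = FALSE]
  cost <- w_cls * l_cls + w_reg * l_reg + 1e5 * !both
  dyn_k <- pmax(1L, floor(apply(iou, 1, function(r)
    sum(sort(r, decreasing = TRUE)[seq_len(min(10, length(r)))]))))
  assign_mat <- matrix(FALSE, ng, length(cand))
  for (g in seq_len(ng)) {
    k <- min(dyn_k[g], length(cand))
    topk <- order(cost[g, ])[seq_len(k)]
    assign_mat[g, topk] <- TRUE
  }
  # a candidate claimed by several gts keeps only its lowest-cost match
  multi <- which(colSums(assign_mat) > 1L)
  for (ci in multi) {
    gbest <- which.min(cost[, ci])
    assign_mat[, ci] <- FALSE
    assign_mat[gbest, ci] <- TRUE
  }
  # a gt stripped of all its picks by the uniqueness rule falls back to
  # its lowest-cost still-unclaimed candidate, so every gt with at least
  # one candidate keeps at least one positive
  for (g in which(rowSums(assign_mat) == 0L)) {
    free <- which(colSums(assign_mat) == 0L)
    if (length(free) == 0L) break
    assign_mat[g, free[which.min(cost[g, free])]] <- TRUE
  }
  pos_c <- which(colSums(assign_mat) > 0L)
  gt_of <- apply(assign_mat[, pos_c, drop = FALSE], 2, which.max)
  list(pos = cand[pos_c], gt_of = gt_of,
       iou = iou[cbind(gt_of, pos_c)],
       dynamic_k = dyn_k, cost = cost, cand = cand,
       fallback = fallback)
}

#' Detection training loss
#'
#' Composite objective `l_total = lambda_reg l_reg + lambda_cls l_cls +
#' lambda_conf l_conf`: IoU loss (1 - IoU) on assigned positives, binary
#' cross-entropy on positive class logits, and binary cross-entropy on all
#' objectness logits with the positive mask as target. All three terms are
#' normalised by the number of positives (the weighted positive/negative
#' balance of the single-stage family).
#'
#' @param outs per-level head outputs.
#' @param gts ground-truth boxes (may have zero rows).
#' @param weights `list(reg = 5, cls = 1, conf = 1)`.
#' @param with_grad also return gradients with respect to the head logits.
#' @return list with `l_total`, `l_reg`, `l_cls`, `l_conf`, `n_pos`,
#'   `no_positives` flag, and (if requested) `grads` in per-level form.
#' @export
detection_loss <- function(outs, gts,
                           weights = list(reg = 5, cls = 1, conf = 1),
                           with_grad = FALSE) {
  fl <- flatten_head(outs)
  n <- length(fl$obj)
  gts <- matrix(gts, ncol = 4)
  obj_target <- numeric(n)
  if (nrow(gts) > 0L) {
    asg <- simota_assign(fl, gts)
    pos <- asg$pos
    obj_target[pos] <- 1
    n_pos <- length(pos)
  } else {
    asg <- NULL; pos <- integer(0); n_pos <- 0L
  }
  norm <- max(1L, n_pos)
  l_conf <- sum(bce_logit(fl$obj, obj_target)) / norm
  if (n_pos > 0L) {
    boxes <- decode_cells(fl)[pos, , drop = FALSE]
    gmat <- gts[asg$gt_of, , drop = FALSE]
    iou <- box_iou(boxes, gmat)
    iou_d <- iou[cbind(seq_len(n_pos), seq_len(n_pos))]
    l_reg <- sum(1 - iou_d) / norm
    l_cls <- sum(bce_logit(fl$cls[pos, 1], 1)) / norm
  } else {
    l_reg <- 0; l_cls <- 0
  }
  l_total <- weights$reg * l_reg + weights$cls * l_cls +
    weights$conf * l_conf
  out <- list(l_total = l_total, l_reg = l_reg, l_cls = l_cls,
              l_conf = l_conf, n_pos = n_pos,
              no_positives = n_pos == 0L && nrow(gts) > 0L)
  if (!with_grad) return(out)

  # gradients w.r.t. logits / raw regression
  d_obj <- weights$conf * (sigmoid(fl$obj) - obj_target) / norm
  d_cls <- numeric(n)
  d_reg <- matrix(0, n, 4)
  if (n_pos > 0L) {
    d_cls[pos] <- weights$cls * (sigmoid(fl$cls[pos, 1]) - 1) / norm
    # d(1 - IoU)/d(raw) through corner-form decode
    s <- fl$stride[pos]
    b <- boxes; g <- gmat
    ix1 <- pmax(b[, 1], g[, 1]); iy1 <- pmax(b[, 2], g[, 2])
    ix2 <- pmin(b[, 3], g[, 3]); iy2 <- pmin(b[, 4], g[, 4])
    iw <- pmax(0, ix2 - ix1); ih <- pmax(0, iy2 - iy1)
    inter <- iw * ih
    ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
    ag <- (g[, 3] - g[, 1]) * (g[, 4] - g[, 2])
    un <- ab + ag - inter
    # dIoU/dI and dIoU/dAb
    dI <- (un + inter) / un^2          # d(I/U)/dI  (U depends on I)
    dAb <- -inter / un^2
    # corner gradients
    act <- iw > 0 & ih > 0
    d_x1 <- -dAb * (b[, 4] - b[, 2]) - dI * ih * as.numeric(act & b[, 1] >= g[, 1])
    d_x2 <-  dAb * (b[, 4] - b[, 2]) + dI * ih * as.numeric(act & b[, 3] <= g[, 3])
    d_y1 <- -dAb * (b[, 3] - b[, 1]) - dI * iw * as.numeric(act & b[, 2] >= g[, 2])
    d_y2 <-  dAb * (b[, 3] - b[, 1]) + dI * iw * as.numeric(act & b[, 4] <= g[, 4])
    # loss is (1 - IoU): flip sign; normalise
    cfac <- -weights$reg / norm
    d_x1 <- cfac * d_x1; d_x2 <- cfac * d_x2
    d_y1 <- cfac * d_y1; d_y2 <- cfac * d_y2
    # chain to raw (dx, dy, dw, dh): cx=(j+dx)s, w=exp(dw)s
    w_b <- b[, 3] - b[, 1]; h_b <- b[, 4] - b[, 2]
    d_cx <- d_x1 + d_x2; d_cy <- d_y1 + d_y2
    d_w <- (-d_x1 + d_x2) / 2; d_h <- (-d_y1 + d_y2) / 2
    d_reg[pos, 1] <- d_cx * s
    d_reg[pos, 2] <- d_cy * s
    d_reg[pos, 3] <- d_w * w_b     # d w / d dw = exp(dw) s = w
    d_reg[pos, 4] <- d_h * h_b
  }
  # reshape gradients to per-level arrays
  grads <- list()
  off <- 0L
  for (l in seq_along(outs)) {
    d <- dim(outs[[l]]$reg)
    nl <- d[1] * d[2]
    idx <- off + seq_len(nl)
    grads[[l]] <- list(
      cls = array(d_cls[idx], dim(outs[[l]]$cls)),
      reg = array(d_reg[idx, ], c(d[1], d[2], 4)),
      obj = array(d_obj[idx], dim(outs[[l]]$obj)))
    off <- off + nl
  }
  out$grads <- grads
  out$assign <- asg
  out
}
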