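# Evaluation: greedy matching, precision/recall/F1 at IoU 0.5 and 0.75,
# COCO-dialect 101-point mAP@50:95, and the 5-fold cross-validation
# harness.

# greedy score-ordered matching of one image's detections to ground
# truths at a single IoU threshold; returns logical TP flags per detection
# (in the given order) and the number of matched gts
match_greedy <- function(det_boxes, det_scores, gt_boxes, iou_thr) {
  nd <- nrow(det_boxes); ng <- nrow(gt_boxes)
  tp <- logical(nd)
  if (nd == 0L || ng == 0L) return(list(tp = tp, n_match = 0L))
  ord <- order(-det_scores, seq_len(nd))
  used <- logical(ng)
  iou <- box_iou(det_boxes, gt_boxes)
  for (i in ord) {
    best <- -1; bj <- 0L
    for (j in seq_len(ng)) {
      if (!used[j] && iou[i, j] >= iou_thr && iou[i, j] > best) {
        best <- iou[i, j]; bj <- j
      }
    }
    if (bj > 0L) { used[bj] <- TRUE; tp[i] <- TRUE }
  }
  list(tp = tp, n_match = sum(used))
}

# 101-point interpolated average precision from score-ranked TP flags
ap_101 <- function(scores, tp, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (length(scores) == 0L) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  rec <- ctp / n_gt
  prec <- ctp / (ctp + cfp)
  # precision envelope, sampled at 101 recall points
  rs <- seq(0, 1, by = 0.01)
  ap <- 0
  for (r in rs) {
    p <- prec[rec >= r]
    ap <- ap + (if (length(p)) max(p) else 0)
  }
  ap / length(rs)
}

#' Evaluate detections against ground truth
#'
#' Computes precision, recall and F1 at IoU thresholds 0.5 and 0.75 (at a
#' fixed operating score threshold), and mAP@50:95 (mean over thresholds
#' 0.50 to 0.95 in steps of 0.05 of the 101-point interpolated average
#' precision), matching detections greedily in descending score order.
#' All quantities are percentages.
#'
#' @param dets per-image list of detection data.frames (columns x1, y1,
#'   x2, y2, score).
#' @param gts per-image list of ground-truth box matrices.
#' @param score_thresh operating point for precision/recall/F1.
#' @return list of class `eval_report`.
#' @export
evaluate_detections <- function(dets, gts, score_thresh = 0.5) {
  stopifnot(length(dets) == length(gts))
  n_img <- length(dets)
  gts <- lapply(gts, function(g) matrix(g, ncol = 4))
  n_gt <- sum(vapply(gts, nrow, integer(1)))
  prf <- function(thr) {
    tp <- 0L; nd <- 0L
    for (i in seq_len(n_img)) {
      d <- dets[[i]]
      d <- d[d$score >= score_thresh, , drop = FALSE]
      nd <- nd + nrow(d)
      if (nrow(d) == 0L) next
      m <- match_greedy(as.matrix(d[, 1:4]), d$score, gts[[i]], thr)
      tp <- tp + sum(m$tp)
    }
    p <- if (nd > 0) tp / nd else NA_real_
    r <- if (n_gt > 0) tp / n_gt else NA_real_
    f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else 0
    c(p = 100 * p, r = 100 * r, f = 100 * f)
  }
  m50 <- prf(0.5); m75 <- prf(0.75)
  # AP over the 10 COCO thresholds using all detections (low threshold)
  thrs <- seq(0.5, 0.95, by = 0.05)
  aps <- vapply(thrs, function(thr) {
    sc <- c(); fl <- c()
    for (i in seq_len(n_img)) {
      d <- dets[[i]]
      if (nrow(d) == 0L) next
      m <- match_greedy(as.matrix(d[, 1:4]), d$score, gts[[i]], thr)
      sc <- c(sc, d$score); fl <- c(fl, m$tp)
    }
    ap_101(sc, fl, n_gt)
  }, numeric(1))
  rep <- list(precision_50 = m50["p"], recall_50 = m50["r"],
              f1_50 = m50["f"], precision_75 = m75["p"],
              recall_75 = m75["r"], f1_75 = m75["f"],
              ap_by_threshold = stats::setNames(100 * aps, thrs),
              map_50_95 = 100 * mean(aps),
              n_images = n_img, n_gt = n_gt,
              score_thresh = score_thresh)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval over %d images (%d ground truths), score >= %.2f\n",
              x$n_images, x$n_gt, x$score_thresh))
  cat(sprintf("  IoU 0.50: P %.2f  R %.2f  F1 %.2f\n", x$precision_50,
              x$recall_50, x$f1_50))
  cat(sprintf("  IoU 0.75: P %.2f  R %.2f  F1 %.2f\n", x$precision_75,
              x$recall_75, x$f1_75))
  cat(sprintf("  mAP@50:95: %.2f\n", x$map_50_95))
  invisible(x)
}

# run a model over a dataset, returning per-image detections + gts
predict_dataset <- function(model, ds, score_thresh = 0.001,
                            nms_iou = 0.65) {
  dets <- lapply(ds, function(s) detect(model, s$image, score_thresh,
                                        nms_iou))
  gts <- lapply(ds, function(s) s$boxes)
  list(dets = dets, gts = gts)
}

#' Evaluate a model on a dataset
#'
#' @param model trained model.
#' @param ds annotated dataset.
#' @param score_thresh operating point for the P/R/F1 columns.
#' @return an `eval_report`.
#' @export
evaluate_model <- function(model, ds, score_thresh = 0.5) {
  pr <- predict_dataset(model, ds)
  evaluate_detections(pr$dets, pr$gts, score_thresh)
}

#' Deterministic 5-fold split
#'
#' Random partition of `n` indices into `k` mutually exclusive subsets of
#' near-equal size. With a fixed seed the same partition is reproduced,
#' so compared models can share identical folds.
#'
#' @param n dataset size.
#' @param k folds.
#' @param seed RNG seed.
#' @return list of `k` integer index vectors.
#' @export
fold_split <- function(n, k = 5L, seed = 1L) {
  stopifnot(n >= k)
  set.seed(seed)
  idx <- sample(n)
  unname(split(idx, rep(seq_len(k), length.out = n)))
}

#' K-fold cross-validation
#'
#' Trains and evaluates one model per fold (one subset held out each
#' round, the rest used for training) through the identical code path,
#' and reports per-fold metrics with their arithmetic mean. Folds with no
#' positive test frames yield NA recall and are excluded from the mean
#' with a warning.
#'
#' @param ds annotated dataset.
#' @param cfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param k number of folds.
#' @param seed seed for the fold split and per-fold model init.
#' @param score_thresh operating point.
#' @return list with `folds` (data.frame of per-fold metrics) and `mean`
#'   (named vector of fold means).
#' @export
cross_validate <- function(ds, cfg, tcfg, k = 5L, seed = 1L,
                           score_thresh = 0.5) {
  folds <- fold_split(length(ds), k, seed)
  rows <- list()
  for (fi in seq_len(k)) {
    test_idx <- folds[[fi]]
    train_idx <- setdiff(seq_along(ds), test_idx)
    model <- build_detector(cfg, tcfg$input_size, seed = seed + fi)
    model <- train_detector(model, ds[train_idx], tcfg)
    test_set <- ds[test_idx]
    if (!any(vapply(test_set, function(s) nrow(s$boxes) > 0, logical(1))))
      warning("fold ", fi, " has no positive test frames; recall is NA")
    ev <- evaluate_model(model, test_set, score_thresh)
    rows[[fi]] <- data.frame(fold = fi,
                             precision_50 = ev$precision_50,
                             recall_50 = ev$recall_50, f1_50 = ev$f1_50,
                             precision_75 = ev$precision_75,
                             recall_75 = ev$recall_75, f1_75 = ev$f1_75,
                             map_50_95 = ev$map_50_95)
  }
  tab <- do.call(rbind, rows)
  mean_row <- colMeans(tab[, -1], na.rm = TRUE)
  list(folds = tab, mean = mean_row)
}
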