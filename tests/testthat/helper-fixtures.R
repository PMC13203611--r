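# shared fixtures and independent oracle implementations

.fixture_env <- new.env()

# memoised small phantom set
fixture_phantoms <- function(n = 8, seed = 11, p_empty = 0, size = 320L) {
  key <- paste("ph", n, seed, p_empty, size, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_phantoms(
      phantom_config(image_size = c(size, size), n_images = n,
                     p_empty = p_empty, seed = seed))
  .fixture_env[[key]]
}

# random head-output fixture for a list of grid sizes
fixture_outs <- function(grids = c(8, 4, 2), seed = 1, sd_reg = 0.5) {
  set.seed(seed)
  lapply(grids, function(g) list(
    cls = array(rnorm(g * g), c(g, g, 1)),
    reg = array(rnorm(g * g * 4, sd = sd_reg), c(g, g, 4)),
    obj = array(rnorm(g * g), c(g, g, 1))))
}

# independent O(n^2) suppression oracle: a box survives iff no surviving
# higher-ranked box overlaps it above the threshold
oracle_nms <- function(boxes, scores, thr) {
  ord <- order(-scores, seq_along(scores))
  alive <- rep(TRUE, length(scores))
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!alive[i]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (alive[j] && box_iou(boxes[i, , drop = FALSE],
                              boxes[j, , drop = FALSE])[1, 1] > thr)
        alive[j] <- FALSE
    }
  }
  ord[alive[ord]]
}

# independently coded evaluator: greedy matching + raw precision/recall
# accumulation and 101-point AP, written from scratch
oracle_eval <- function(dets, gts, thr) {
  recs <- list()
  n_gt <- 0L
  for (i in seq_along(dets)) {
    d <- dets[[i]]; g <- matrix(gts[[i]], ncol = 4)
    n_gt <- n_gt + nrow(g)
    if (nrow(d) == 0) next
    taken <- rep(FALSE, nrow(g))
    for (k in order(-d$score)) {
      hit <- 0L; best <- thr - 1e-12
      if (nrow(g) > 0) for (j in seq_len(nrow(g))) {
        v <- box_iou(as.matrix(d[k, 1:4]), g[j, , drop = FALSE])[1, 1]
        if (!taken[j] && v >= thr && v > best) { best <- v; hit <- j }
      }
      if (hit > 0L) taken[hit] <- TRUE
      recs[[length(recs) + 1L]] <- c(d$score[k], hit > 0L)
    }
  }
  if (length(recs) == 0L) return(list(ap = 0, n_gt = n_gt))
  m <- do.call(rbind, recs)
  m <- m[order(-m[, 1]), , drop = FALSE]
  tp <- cumsum(m[, 2]); fp <- cumsum(1 - m[, 2])
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  ap <- mean(vapply(seq(0, 1, 0.01), function(r) {
    p <- prec[rec >= r]; if (length(p)) max(p) else 0
  }, numeric(1)))
  list(ap = ap, n_gt = n_gt)
}

# exhaustive minimal-total-cost assignment: exactly k[g] distinct
# candidates per ground truth, candidates disjoint across ground truths
oracle_assign <- function(cost, ks) {
  ng <- nrow(cost); nc <- ncol(cost)
  best <- NULL; best_cost <- Inf
  rec <- function(g, used, acc, sel) {
    if (g > ng) {
      if (acc < best_cost) { best_cost <<- acc; best <<- sel }
      return(invisible(NULL))
    }
    free <- setdiff(seq_len(nc), used)
    if (length(free) < ks[g]) return(invisible(NULL))
    for (ch in utils::combn(free, ks[g], simplify = FALSE)) {
      rec(g + 1L, c(used, ch), acc + sum(cost[g, ch]),
          c(sel, list(ch)))
    }
  }
  rec(1L, integer(0), 0, list())
  list(sel = best, cost = best_cost)
}
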