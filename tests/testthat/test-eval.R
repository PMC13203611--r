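# Evaluation metrics and the cross-validation harness.

perfect_case <- function() {
  gts <- list(rbind(c(5, 5, 25, 25), c(40, 10, 70, 50)),
              rbind(c(12, 30, 44, 60)))
  dets <- lapply(gts, function(g)
    data.frame(x1 = g[, 1], y1 = g[, 2], x2 = g[, 3], y2 = g[, 4],
               score = 1, label = 1L))
  list(dets = dets, gts = gts)
}

test_that("a perfect detector scores 100 everywhere", {
  pc <- perfect_case()
  ev <- evaluate_detections(pc$dets, pc$gts)
  expect_equal(unname(ev$precision_50), 100)
  expect_equal(unname(ev$recall_50), 100)
  expect_equal(unname(ev$f1_75), 100)
  expect_equal(ev$map_50_95, 100)
})

test_that("a 0.6-IoU match is a TP at 0.5 and an FP+FN at 0.75", {
  gts <- list(rbind(c(0, 0, 10, 10)))
  dets <- list(data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 6, score = 0.9,
                          label = 1L))
  expect_equal(box_iou(as.matrix(dets[[1]][, 1:4]), gts[[1]])[1, 1], 0.6)
  ev <- evaluate_detections(dets, gts)
  expect_equal(unname(ev$precision_50), 100)
  expect_equal(unname(ev$recall_50), 100)
  expect_equal(unname(ev$precision_75), 0)
  expect_equal(unname(ev$recall_75), 0)
})

test_that("F1 is the harmonic mean of its precision and recall", {
  set.seed(12)
  gts <- lapply(1:6, function(i) {
    n <- sample(0:3, 1)
    if (n == 0) return(matrix(numeric(0), 0, 4))
    x <- runif(n, 0, 80); y <- runif(n, 0, 80)
    cbind(x, y, x + runif(n, 8, 30), y + runif(n, 8, 30))
  })
  dets <- lapply(gts, function(g) {
    k <- sample(1:3, 1)
    x <- runif(k, 0, 80); y <- runif(k, 0, 80)
    junk <- data.frame(x1 = x, y1 = y, x2 = x + runif(k, 8, 30),
                       y2 = y + runif(k, 8, 30), score = runif(k, 0.6, 1),
                       label = 1L)
    if (nrow(g) > 0)  # jittered copies of the truths guarantee matches
      junk <- rbind(junk, data.frame(
        x1 = g[, 1] + 0.5, y1 = g[, 2], x2 = g[, 3] + 0.5, y2 = g[, 4],
        score = runif(nrow(g), 0.6, 1), label = 1L))
    junk
  })
  ev <- evaluate_detections(dets, gts)
  checked <- 0L
  for (sfx in c("50", "75")) {
    p <- ev[[paste0("precision_", sfx)]]; r <- ev[[paste0("recall_", sfx)]]
    f <- ev[[paste0("f1_", sfx)]]
    if (!is.na(p) && !is.na(r) && p + r > 0) {
      expect_equal(unname(f), unname(2 * p * r / (p + r)))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 1L)
})

test_that("average precision matches an independently coded matcher", {
  set.seed(33)
  for (rep in 1:3) {
    gts <- lapply(1:20, function(i) {
      n <- sample(0:3, 1)
      if (n == 0) return(matrix(numeric(0), 0, 4))
      x <- runif(n, 0, 100); y <- runif(n, 0, 100)
      cbind(x, y, x + runif(n, 10, 40), y + runif(n, 10, 40))
    })
    dets <- lapply(gts, function(g) {
      base <- if (nrow(g) > 0 && runif(1) < 0.8)
        g + matrix(rnorm(length(g), sd = 3), nrow(g)) else NULL
      k <- sample(0:2, 1)
      x <- runif(k, 0, 100); y <- runif(k, 0, 100)
      junk <- cbind(x, y, x + runif(k, 10, 40), y + runif(k, 10, 40))
      all <- rbind(base, junk)
      if (is.null(all) || nrow(all) == 0)
        return(data.frame(x1 = numeric(0), y1 = numeric(0),
                          x2 = numeric(0), y2 = numeric(0),
                          score = numeric(0), label = integer(0)))
      data.frame(x1 = all[, 1], y1 = all[, 2], x2 = all[, 3],
                 y2 = all[, 4], score = runif(nrow(all)), label = 1L)
    })
    ev <- evaluate_detections(dets, gts)
    for (thr in c(0.5, 0.75, 0.95)) {
      orc <- oracle_eval(dets, gts, thr)
      expect_equal(unname(ev$ap_by_threshold[as.character(thr)]),
                   100 * orc$ap, tolerance = 1e-9)
    }
  }
})

test_that("mAP reacts monotonically to extra detections", {
  gts <- list(rbind(c(5, 5, 25, 25), c(50, 50, 80, 80)))
  d0 <- data.frame(x1 = 5, y1 = 5, x2 = 25, y2 = 25, score = 0.8,
                   label = 1L)
  base <- evaluate_detections(list(d0), gts)
  # adding a correct detection never lowers AP at any threshold
  d1 <- rbind(d0, data.frame(x1 = 50, y1 = 50, x2 = 80, y2 = 80,
                             score = 0.7, label = 1L))
  up <- evaluate_detections(list(d1), gts)
  expect_true(all(up$ap_by_threshold >= base$ap_by_threshold - 1e-12))
  # a zero-overlap false positive at top score never raises AP
  d2 <- rbind(d1, data.frame(x1 = 200, y1 = 200, x2 = 230, y2 = 230,
                             score = 0.99, label = 1L))
  down <- evaluate_detections(list(d2), gts)
  expect_true(all(down$ap_by_threshold <= up$ap_by_threshold + 1e-12))
})

test_that("fold splits are disjoint, covering, balanced and reproducible", {
  f <- fold_split(10, 5, seed = 4)
  expect_equal(length(f), 5)
  expect_true(all(vapply(f, length, integer(1)) == 2))
  expect_equal(sort(unlist(f)), 1:10)
  expect_identical(f, fold_split(10, 5, seed = 4))
  f2 <- fold_split(23, 5, seed = 9)
  expect_equal(sort(unlist(f2)), 1:23)
  expect_true(max(vapply(f2, length, integer(1))) -
                min(vapply(f2, length, integer(1))) <= 1)
})

test_that("cross-validation reports per-fold metrics and their mean", {
  ds <- fixture_phantoms(n = 10, seed = 55, p_empty = 0, size = 96L)
  tc <- train_config(total_epochs = 1L, batch_size = 2L,
                     input_size = c(96L, 96L), use_mosaic = FALSE,
                     use_mixup = FALSE, seed = 3)
  cvr <- cross_validate(ds, model_config("nano-lite"), tc, k = 5L,
                        seed = 3)
  expect_equal(nrow(cvr$folds), 5)
  expect_equal(unname(cvr$mean["f1_50"]),
               mean(cvr$folds$f1_50, na.rm = TRUE))
  expect_true(all(cvr$folds$map_50_95 >= 0 & cvr$folds$map_50_95 <= 100))
})
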