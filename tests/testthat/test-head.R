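# Decoding, IoU/NMS, SimOTA assignment and the composite loss.

test_that("decoding follows the anchor-free formula", {
  g <- 4L
  outs <- list(list(cls = array(10, c(g, g, 1)),
                    reg = array(0, c(g, g, 4)),
                    obj = array(10, c(g, g, 1))))
  d <- decode_detections(outs, strides = 8L)
  # cell (0, 0): centre (0, 0), w = h = 8
  r1 <- d[d$x1 == -4 & d$y1 == -4, ]
  expect_equal(nrow(r1), 1)
  expect_equal(unlist(r1[1, 1:4]), c(x1 = -4, y1 = -4, x2 = 4, y2 = 4))
  # cell (i=4, j=4) with reg (0.5, 0.5, ln 2, ln 2) at stride 8
  outs2 <- list(list(cls = array(10, c(8, 8, 1)),
                     reg = array(0, c(8, 8, 4)),
                     obj = array(-20, c(8, 8, 1))))
  outs2[[1]]$obj[5, 5, 1] <- 10
  outs2[[1]]$reg[5, 5, ] <- c(0.5, 0.5, log(2), log(2))
  d2 <- decode_detections(outs2, strides = 8L, score_thresh = 0.5)
  expect_equal(nrow(d2), 1)
  expect_equal(unlist(d2[1, 1:4]), c(x1 = 28, y1 = 28, x2 = 44, y2 = 44))
  # all objectness at -Inf-like levels: empty set after thresholding
  outs3 <- list(list(cls = array(0, c(g, g, 1)),
                     reg = array(0, c(g, g, 4)),
                     obj = array(-50, c(g, g, 1))))
  expect_equal(nrow(decode_detections(outs3, 8L, score_thresh = 0.001)), 0)
  # non-finite logits are an error
  outs3[[1]]$obj[1] <- NaN
  expect_error(decode_detections(outs3, 8L), "non-finite")
})

test_that("a 640 input yields 8400 predictions over the three levels", {
  outs <- lapply(c(80, 40, 20), function(g) list(
    cls = array(0, c(g, g, 1)), reg = array(0, c(g, g, 4)),
    obj = array(0, c(g, g, 1))))
  fl <- sonolite:::flatten_head(outs)
  expect_equal(length(fl$obj), 8400)
  expect_equal(dim(fl$cls)[2], 1)
})

test_that("encoding a box at its centre cell round-trips through decode", {
  gt <- c(37, 53, 91, 120)
  s <- 8
  cx <- (gt[1] + gt[3]) / 2; cy <- (gt[2] + gt[4]) / 2
  j <- floor(cx / s); i <- floor(cy / s)
  g <- 20L
  outs <- list(list(cls = array(10, c(g, g, 1)),
                    reg = array(0, c(g, g, 4)),
                    obj = array(-30, c(g, g, 1))))
  outs[[1]]$obj[i + 1, j + 1, 1] <- 10
  outs[[1]]$reg[i + 1, j + 1, ] <- c(cx / s - j, cy / s - i,
                                     log((gt[3] - gt[1]) / s),
                                     log((gt[4] - gt[2]) / s))
  d <- decode_detections(outs, s, score_thresh = 0.5)
  expect_equal(unname(unlist(d[1, 1:4])), gt, tolerance = 1e-12)
})

test_that("IoU is reflexive, symmetric and zero on disjoint boxes", {
  set.seed(5)
  for (t in 1:25) {
    a <- sort(runif(2, 0, 50)); b <- sort(runif(2, 0, 50))
    box <- c(a[1], b[1], a[2] + 1, b[2] + 1)
    expect_equal(box_iou(box, box)[1, 1], 1)
    box2 <- box + c(runif(1, -10, 10), runif(1, -10, 10), 0, 0)[c(1, 2, 1, 2)]
    expect_equal(box_iou(box, box2), t(box_iou(box2, box)))
    disj <- box + c(100, 0, 100, 0)
    expect_equal(box_iou(box, disj)[1, 1], 0)
  }
})

test_that("greedy NMS matches the exhaustive suppression oracle", {
  # two identical boxes: the higher-scored one survives
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(nms(b, c(0.9, 0.8), 0.65), 1L)
  # disjoint boxes all survive
  b2 <- rbind(c(0, 0, 10, 10), c(20, 20, 30, 30), c(50, 0, 60, 10))
  expect_equal(sort(nms(b2, c(0.5, 0.9, 0.7), 0.65)), 1:3)
  set.seed(9)
  for (t in 1:10) {
    n <- 10
    x <- runif(n, 0, 60); y <- runif(n, 0, 60)
    w <- runif(n, 5, 25); h <- runif(n, 5, 25)
    boxes <- cbind(x, y, x + w, y + h)
    sc <- runif(n)
    expect_equal(sort(nms(boxes, sc, 0.5)), sort(oracle_nms(boxes, sc, 0.5)))
  }
})

test_that("SimOTA matches exhaustive minimal-cost assignment on toys", {
  set.seed(21)
  for (t in 1:5) {
    # two spatially separated ground truths on one small grid (5 x 5
    # cells at stride 8): top-k neighbourhoods cannot collide, so the
    # greedy dynamic-k selection must coincide with the global optimum
    outs <- fixture_outs(c(5), seed = 100 + t, sd_reg = 0.3)
    gts <- rbind(c(1, 1, 13, 14), c(24, 23, 38, 39)) + runif(2, -1, 1)
    asg <- simota_assign(outs, gts)
    or <- oracle_assign(asg$cost, asg$dynamic_k)
    expect_equal(sum(asg$cost[cbind(asg$gt_of, match(asg$pos, asg$cand))]),
                 or$cost, tolerance = 1e-9)
    expect_equal(length(asg$pos), sum(asg$dynamic_k))
    # every ground truth keeps at least one positive
    expect_true(all(seq_len(nrow(gts)) %in% asg$gt_of))
  }
  # single gt, single candidate: assigned regardless of cost
  outs1 <- fixture_outs(c(2), seed = 5)
  a1 <- simota_assign(outs1, rbind(c(1, 1, 6, 6)))
  expect_gte(length(a1$pos), 1)
})

test_that("the composite loss combines its terms with weights 5, 1, 1", {
  outs <- fixture_outs(seed = 3)
  gts <- rbind(c(10, 12, 40, 45))
  r <- detection_loss(outs, gts)
  expect_equal(r$l_total, 5 * r$l_reg + r$l_cls + r$l_conf)
  # linearity: scaling all three weights scales the total
  r3 <- detection_loss(outs, gts, weights = list(reg = 15, cls = 3, conf = 3))
  expect_equal(r3$l_total, 3 * r$l_total)
  # a prediction exactly on its ground truth contributes zero IoU loss
  g <- 8L; s <- 8
  outs2 <- list(list(cls = array(12, c(g, g, 1)),
                     reg = array(0, c(g, g, 4)),
                     obj = array(-12, c(g, g, 1))))
  gt <- c(20, 20, 36, 36)  # centred on cell (3, 3) with w = h = 2 s
  outs2[[1]]$reg[4, 4, ] <- c(0.5, 0.5, log(2), log(2))
  outs2[[1]]$obj[4, 4, 1] <- 12
  r2 <- detection_loss(outs2, rbind(gt))
  expect_lt(r2$l_reg, 1e-6)
  # zero ground truths: conf term only, flag clear
  r0 <- detection_loss(outs, matrix(0, 0, 4))
  expect_equal(r0$l_reg, 0)
  expect_equal(r0$l_cls, 0)
  expect_gt(r0$l_conf, 0)
  expect_equal(r0$n_pos, 0)
})

test_that("single-cell objectness loss equals closed-form cross-entropy", {
  outs <- list(list(cls = array(0.3, c(1, 1, 1)),
                    reg = array(0, c(1, 1, 4)),
                    obj = array(-0.7, c(1, 1, 1))))
  r <- detection_loss(outs, matrix(0, 0, 4))
  expect_equal(r$l_conf, -log(1 - sigmoid(-0.7)), tolerance = 1e-12)
})

test_that("loss gradients agree with finite differences", {
  outs <- fixture_outs(seed = 10)
  gts <- rbind(c(10, 12, 40, 45), c(30, 5, 60, 30))
  r <- detection_loss(outs, gts, with_grad = TRUE)
  set.seed(77)
  eps <- 1e-5
  for (t in 1:25) {
    l <- sample(3, 1); comp <- sample(c("cls", "reg", "obj"), 1)
    j <- sample(length(outs[[l]][[comp]]), 1)
    op <- outs; op[[l]][[comp]][j] <- op[[l]][[comp]][j] + eps
    om <- outs; om[[l]][[comp]][j] <- om[[l]][[comp]][j] - eps
    num <- (detection_loss(op, gts)$l_total -
              detection_loss(om, gts)$l_total) / (2 * eps)
    expect_equal(r$grads[[l]][[comp]][j], num, tolerance = 1e-4)
  }
})
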