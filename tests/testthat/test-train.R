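# Learning-rate schedule and the training loop.

test_that("the schedule warms up quadratically then steps down", {
  cfg <- train_config(total_epochs = 100L)
  expect_equal(lr_at(0, cfg), 0)
  expect_equal(lr_at(2.5, cfg), 1e-2 * 0.25)
  expect_equal(lr_at(5, cfg), 1e-2)
  expect_equal(lr_at(59.9, cfg), 1e-2)
  expect_equal(lr_at(60, cfg), 1e-3)
  expect_equal(lr_at(85, cfg), 1e-4)
  expect_equal(lr_at(99, cfg), 1e-4)
  # drop points are validated
  expect_error(train_config(lr_drop_points = c(0.9, 0.6)))
})

test_that("one optimisation step on a fixed toy batch decreases the loss", {
  ds <- fixture_phantoms(n = 2, seed = 77, p_empty = 0, size = 96L)
  md <- build_detector(model_config("nano-lite"), c(96L, 96L), seed = 2)
  state <- sonolite:::sgd_state(md)
  loss_of <- function() {
    tot <- 0
    for (s in ds) {
      outs <- md$forward(sonolite:::frame_to_input(s$image), TRUE)
      tot <- tot + detection_loss(outs, s$boxes)$l_total
    }
    tot
  }
  l0 <- loss_of()
  sonolite:::zero_grads(md)
  for (s in ds) {
    outs <- md$forward(sonolite:::frame_to_input(s$image), TRUE)
    r <- detection_loss(outs, s$boxes, with_grad = TRUE)
    md$backward(r$grads)
  }
  sonolite:::sgd_step(md, state, lr = 5e-4, momentum = 0, weight_decay = 0)
  expect_lt(loss_of(), l0)
})

test_that("training is bit-reproducible for a fixed seed", {
  ds <- fixture_phantoms(n = 2, seed = 78, p_empty = 0, size = 96L)
  run <- function() {
    md <- build_detector(model_config("nano-lite"), c(96L, 96L), seed = 4)
    tc <- train_config(total_epochs = 1L, batch_size = 2L,
                       input_size = c(96L, 96L), seed = 4)
    train_detector(md, ds, tc)$history$l_total[1]
  }
  a <- run(); b <- run()
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("weights survive a save/load round trip", {
  md <- build_detector(model_config("nano-lite"), c(96L, 96L), seed = 6)
  ds <- fixture_phantoms(n = 2, seed = 79, p_empty = 0, size = 96L)
  p <- withr::local_tempfile(fileext = ".rds")
  save_weights(md, p)
  d1 <- detect(md, ds[[1]]$image, score_thresh = 0.001)
  md2 <- build_detector(model_config("nano-lite"), c(96L, 96L), seed = 999)
  load_weights(md2, p)
  d2 <- detect(md2, ds[[1]]$image, score_thresh = 0.001)
  expect_equal(d1, d2)
})
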