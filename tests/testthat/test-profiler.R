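# Analytic parameter / FLOPs accounting.

test_that("baseline parameter counts are integer-exact", {
  expect_equal(count_params(model_config("tiny")), 5032866)
  expect_equal(count_params(model_config("nano")), 896754)
})

test_that("parameter count equals direct enumeration of model scalars", {
  for (v in c("tiny-lite", "nano-lite")) {
    md <- build_detector(model_config(v), c(64L, 64L), seed = 1)
    alloc <- sum(vapply(md$ctx$mods, function(m) {
      n <- 0L
      for (f in intersect(c("w", "g", "b"), ls(m)))
        n <- n + length(m[[f]])
      n
    }, numeric(1)))
    expect_equal(count_params(md), alloc)
    expect_equal(count_params(model_config(v)), alloc)
  }
})

test_that("octave convolutions conserve the plain-convolution weight count", {
  for (cin in c(8L, 16L, 48L)) for (cout in c(8L, 32L)) {
    for (k in c(1L, 3L)) for (a in c(0.2, 0.4, 0.5, 0.6, 0.8)) {
      ctx <- sonolite:::new_net_ctx(alloc = FALSE)
      sonolite:::o_conv(ctx, cin, cout, k, 1L, c(16L, 16L), a, a)
      df <- sonolite:::ctx_layer_table(ctx)
      w <- sum(ifelse(df$kind == "conv",
                      df$cin / df$groups * df$cout * df$k^2, 0))
      expect_equal(w, cin * cout * k^2)
    }
  }
})

test_that("model size is invariant to the channel allocation ratio", {
  counts <- vapply(c(0.2, 0.4, 0.5, 0.6, 0.8), function(a)
    count_params(model_config("tiny-lite", alpha = a)), numeric(1))
  expect_true(all(counts == counts[1]))
})

test_that("FLOPs strictly decrease as alpha grows", {
  fl <- vapply(c(0.2, 0.4, 0.5, 0.6, 0.8), function(a)
    count_flops(model_config("tiny-lite", alpha = a)), numeric(1))
  expect_true(all(diff(fl) < 0))
})

test_that("calibration closure reproduces the compact baselines within 1%", {
  cv <- calibrate_convention()
  expect_lt(cv$max_rel_err, 0.01)
  expect_equal(cv$input_size, c(512L, 512L))
  expect_equal(cv$mac_factor, 1)
})

test_that("doubling the input side quadruples convolution MACs", {
  cfg <- model_config("tiny")
  m1 <- build_detector(cfg, c(256L, 256L), alloc = FALSE)
  m2 <- build_detector(cfg, c(512L, 512L), alloc = FALSE)
  macs <- function(md) {
    df <- sonolite:::ctx_layer_table(md$ctx)
    sonolite:::rows_macs(df)
  }
  expect_equal(macs(m2) / macs(m1), 4)
})

test_that("per-module breakdown sums to the model total", {
  rep <- profile_model(model_config("tiny-lite"))
  expect_equal(sum(rep$breakdown$params_m), rep$params_m)
  expect_equal(sum(rep$breakdown$flops_g), rep$flops_g, tolerance = 1e-12)
})

test_that("simple layer counting follows the closed form", {
  # one 3x3 conv 16->32 with norm: 16*32*9 + 2*32 scalars;
  # on a 40x40 output: 16*32*9*1600 MACs
  ctx <- sonolite:::new_net_ctx(alloc = FALSE)
  sonolite:::base_conv(ctx, 16L, 32L, 3L, 1L, c(40L, 40L))
  df <- sonolite:::ctx_layer_table(ctx)
  expect_equal(sonolite:::rows_params(df), 16 * 32 * 9 + 2 * 32)
  expect_equal(sonolite:::rows_macs(df), 16 * 32 * 9 * 1600)
})
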