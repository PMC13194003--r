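test_that("default output shapes follow the pyramid schedule", {
  sh <- layer_output_shapes(hpr_config())
  expect_equal(sh$channels[-1], c(64, 64, 128, 128, 256, 256, 512, 512, 1024))
  expect_equal(sh$length[-1], c(128, 64, 32, 16, 8, 4, 2, 1, 1))
  # stride arithmetic at L = 256: eight stride-2 stages take 256 to 1
  sh2 <- layer_output_shapes(hpr_config(), input_len = 256L)
  expect_equal(sh2$length[-1], c(256, 128, 64, 32, 16, 8, 4, 2, 1))
  # all strides 1 preserves length everywhere
  sh3 <- layer_output_shapes(hpr_config(layer_strides = rep(1L, 9)))
  expect_true(all(sh3$length == 128))
})

test_that("model construction matches the configured block counts", {
  m <- build_model(hpr_config(num_classes = 4L))
  expect_length(m$layers, 9L)
  expect_equal(vapply(m$layers, length, 0L),
               stats::setNames(c(3L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 3L),
                               names(m$layers)))
  expect_equal(sum(vapply(m$layers, length, 0L)), 34L)

  m1 <- build_model(hpr_config(reb_counts = rep(1L, 9)))
  expect_equal(sum(vapply(m1$layers, length, 0L)), 9L)

  expect_error(hpr_config(reb_counts = c(1L, 1L),
                          layer_channels = list(c(32L, 64L), c(128L, 256L)),
                          layer_strides = c(1L, 2L)),
               "channel schedule mismatch")
  expect_error(hpr_config(kernel = 16L), "odd")
})

test_that("forward pass is normalised, finite and batch independent", {
  set.seed(2)
  m <- build_model(tiny_cfg())
  z <- forward_model(m, matrix(0, 4, 32))
  expect_true(all(is.finite(z$logits)))
  expect_equal(rowSums(z$probs), rep(1, 4), tolerance = 1e-6)

  beat <- stats::rnorm(32)
  one <- forward_model(m, matrix(beat, 1, 32))
  eight <- forward_model(m, matrix(beat, 8, 32, byrow = TRUE))
  for (b in 1:8)
    expect_equal(eight$logits[b, ], one$logits[1, ], tolerance = 1e-10)

  expect_error(forward_model(m, matrix(0, 2, 20)), "expects L = 32")
})

test_that("closed-form accounting equals built-model enumeration", {
  set.seed(99)
  for (rep in 1:20) {
    cfg <- random_small_cfg()
    expect_equal(nonzero_count(build_model(cfg)), count_parameters(cfg))
  }
})

test_that("a REB's output is the elementwise sum of its two branches", {
  set.seed(5)
  m <- build_model(tiny_cfg())
  reb <- m$layers[[1]][[1]]
  x <- array(stats::rnorm(4 * 32 * 2), c(4, 32, 2))
  full <- hprnet:::reb_fwd(reb, x, train = FALSE)$y

  main_only <- reb
  main_only$skip$W[] <- 0                      # zero the skip conv -> branch dies
  main <- hprnet:::reb_fwd(main_only, x, train = FALSE)$y

  skip_only <- reb
  skip_only$conv2$W[] <- 0                     # main branch ends in conv2
  skip <- hprnet:::reb_fwd(skip_only, x, train = FALSE)$y

  expect_equal(main + skip, full, tolerance = 1e-10)

  # identity-skip REB: the skip branch is exactly the max pool of the input
  reb2 <- m$layers[[1]][[2]]
  x2 <- full
  full2 <- hprnet:::reb_fwd(reb2, x2, train = FALSE)$y
  zero_main <- reb2
  zero_main$conv2$W[] <- 0
  skip2 <- hprnet:::reb_fwd(zero_main, x2, train = FALSE)$y
  expect_equal(skip2, hprnet:::pool3_fwd(x2)$y, tolerance = 1e-10)
})

test_that("FLOP accounting follows the documented 2*MAC convention", {
  cfg <- tiny_cfg()
  # independent arithmetic over the same architecture
  k <- cfg$kernel
  len0 <- 32
  expected <- 2 * 1 * 4 * k * len0                       # front conv
  lens <- c(32, 16)
  expected <- expected +
    2 * (4 * 6 + 6 * 6) * k * 32 + 2 * 4 * 6 * 32 +      # L1 REB1 (+ skip)
    2 * (6 * 6 + 6 * 6) * k * 32 +                       # L1 REB2
    2 * (6 * 8 + 8 * 8) * k * 16 + 2 * 6 * 8 * 16 +      # L2 REB1 (+ skip)
    2 * 8 * 3                                            # fully connected
  expect_equal(count_flops(cfg), expected / 1e6, tolerance = 1e-12)

  # doubling input length on a stride-1 config doubles the conv cost exactly
  cfg1 <- hpr_config(input_len = 64L, front_channels = 4L, kernel = 5L,
                     reb_counts = c(1L), layer_channels = list(c(4L, 6L)),
                     layer_strides = 1L, num_classes = 3L)
  cfg2 <- hpr_config(input_len = 128L, front_channels = 4L, kernel = 5L,
                     reb_counts = c(1L), layer_channels = list(c(4L, 6L)),
                     layer_strides = 1L, num_classes = 3L)
  fc_cost <- 2 * 6 * 3 / 1e6
  expect_equal(count_flops(cfg2) - fc_cost, 2 * (count_flops(cfg1) - fc_cost),
               tolerance = 1e-12)
})

test_that("forward/backward gradients agree with numerical differentiation", {
  set.seed(42)
  cfg <- tiny_cfg()
  m <- build_model(cfg)
  x <- matrix(stats::rnorm(3 * 32), 3, 32)
  y <- c(1L, 2L, 3L)
  fw <- forward_model(m, x, train = TRUE, keep_cache = TRUE)
  lo <- hprnet:::ce_loss_grad(t(fw$logits), y)
  bw <- hprnet:::backward_model(fw$model, fw$cache, t(lo$dlogits))
  lossfn <- function(model) {
    f <- forward_model(model, x, train = TRUE)
    hprnet:::ce_loss_grad(t(f$logits), y)$loss
  }
  slots <- hprnet:::param_slots(m)
  for (s in sample(seq_along(slots), 8)) {
    sl <- slots[[s]]
    w <- hprnet:::get_at(m, sl$path)
    i <- sample(length(w), 1)
    eps <- 1e-5
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    g_num <- (lossfn(hprnet:::set_at(m, sl$path, wp)) -
                lossfn(hprnet:::set_at(m, sl$path, wm))) / (2 * eps)
    g_an <- hprnet:::get_at(bw$grads, sl$path)[i]
    expect_equal(g_an, g_num, tolerance = 1e-5)
  }
})
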