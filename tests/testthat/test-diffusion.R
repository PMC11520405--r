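test_that("make_schedule hits the stated endpoints and validates input", {
  s <- make_schedule(1000L, 1e-4, 0.05)
  expect_equal(s$beta[1], 1e-4)
  expect_equal(s$beta[1000], 0.05)
  expect_true(all(diff(s$beta) > 0))
  expect_true(all(s$beta > 0 & s$beta < 1))
  expect_true(all(diff(s$alpha_bar) < 0))
  expect_error(make_schedule(10, 0.05, 1e-4), "beta_start < beta_end")
  expect_error(make_schedule(1L), "T must be >= 2")
  s2 <- make_schedule(2L, 1e-4, 0.05)
  expect_equal(s2$beta, c(1e-4, 0.05))
  expect_equal(s2$alpha_bar[2], (1 - 1e-4) * (1 - 0.05))
})

test_that("alpha_bar matches a cumulative-product oracle to 1e-12", {
  for (T in c(2L, 7L, 200L, 1000L)) {
    s <- make_schedule(T)
    ab <- 1
    oracle <- numeric(T)
    for (t in 1:T) {
      ab <- ab * (1 - s$beta[t])
      oracle[t] <- ab
    }
    expect_lt(max(abs(s$alpha_bar - oracle) / oracle), 1e-12)
  }
})

test_that("q_sample follows the closed-form marginal", {
  s <- make_schedule(200L)
  x0 <- matrix(seq(-1, 1, length.out = 16), 4)
  expect_equal(q_sample(x0, 1, matrix(0, 4, 4), s), sqrt(s$alpha_bar[1]) * x0)
  eps <- matrix(rnorm(16), 4)
  expect_equal(q_sample(matrix(0, 4, 4), 100, eps, s),
               sqrt(1 - s$alpha_bar[100]) * eps)
  expect_error(q_sample(x0, 0, eps, s), "out of range")
  expect_error(q_sample(x0, 201, eps, s), "out of range")
  expect_error(q_sample(x0, 5, matrix(0, 2, 2), s), "shape")
})

test_that("0-step training returns the seeded initialization", {
  ds <- make_pair_dataset(desk_scene(n_cells = 1L), desk_defocus(),
                          n_pairs = 3, seed = 1)
  m <- train_ddpm(ds$pairs, tiny_denoiser(), tiny_schedule(),
                  diffusion_config(steps = 0L), seed = 9)
  expect_length(m$history, 0)
  init <- get("with_seed", asNamespace("refocus"))(
    9, get("init_denoiser_net", asNamespace("refocus"))(tiny_denoiser(), 3L))
  expect_equal(m$params[[1]]$W, init[[1]]$W)
})

test_that("toy denoiser beats the trivial eps-hat = 0 predictor", {
  # 16x16 toy task: condition equals the target
  img <- matrix(rep(c(0.2, 0.8), each = 8 * 16), 16)
  pairs <- lapply(1:8, function(i) list(in_focus = img, oof = img))
  sched <- make_schedule(20L)
  m <- train_ddpm(pairs, denoiser_spec(base_channels = 6L, n_layers = 2L),
                  sched,
                  diffusion_config(steps = 120L, batch_size = 4L,
                                   learning_rate = 3e-3), seed = 2)
  # validation MSE of noise prediction over fresh draws
  pn <- get("predict_noise", asNamespace("refocus"))
  set.seed(3)
  mses <- vapply(1:20, function(i) {
    t <- sample(20, 1)
    eps <- matrix(rnorm(256), 16)
    xt <- q_sample(2 * img - 1, t, eps, sched)
    mean((pn(m, xt, 2 * img - 1, t) - eps)^2)
  }, numeric(1))
  expect_lt(mean(mses), 1.0)
  expect_lt(mean(tail(m$history, 10)), mean(head(m$history, 10)))
})

test_that("sampling is seed-deterministic and seed-sensitive", {
  ds <- make_pair_dataset(desk_scene(n_cells = 1L), desk_defocus(),
                          n_pairs = 2, seed = 4)
  m <- train_ddpm(ds$pairs, tiny_denoiser(), tiny_schedule(),
                  diffusion_config(steps = 5L, batch_size = 2L), seed = 5)
  cond <- ds$pairs[[1]]$oof
  a <- p_sample_loop(m, cond, seed = 7)
  b <- p_sample_loop(m, cond, seed = 7)
  d <- p_sample_loop(m, cond, seed = 8)
  expect_identical(a, b)
  expect_gt(max(abs(a - d)), 0)
  expect_true(all(a >= 0 & a <= 1))
  # schedule length mismatch is caught
  expect_error(p_sample_loop(m, cond, seed = 1,
                             schedule = make_schedule(7L)), "does not match")
})

test_that("restore_averaged: K = 1 degenerates, sub-seeds differ", {
  ds <- make_pair_dataset(desk_scene(n_cells = 1L), desk_defocus(),
                          n_pairs = 2, seed = 6)
  m <- train_ddpm(ds$pairs, tiny_denoiser(), tiny_schedule(),
                  diffusion_config(steps = 5L, batch_size = 2L), seed = 6)
  cond <- ds$pairs[[1]]$oof
  r1 <- restore_averaged(m, cond, K = 1L, seed = 1)
  expect_identical(r1$mean_image, r1$samples[[1]])
  expect_true(all(r1$std_image == 0))
  r3 <- restore_averaged(m, cond, K = 3L, seed = 1)
  expect_false(identical(r3$samples[[1]], r3$samples[[2]]))
  expect_equal(r3$mean_image,
               (r3$samples[[1]] + r3$samples[[2]] + r3$samples[[3]]) / 3)
  expect_error(restore_averaged(m, cond, K = 0L), "K must be >= 1")
})

test_that("charbonnier: floor at equality, bounds |d| from above", {
  a <- matrix(runif(16), 4)
  expect_equal(charbonnier(a, a, eps = 1e-3), 1e-3)
  b <- matrix(runif(16), 4)
  expect_gte(charbonnier(a, b, eps = 1e-3), mean(abs(a - b)))
  expect_equal(charbonnier(a, b, eps = 1e-12), mean(abs(a - b)),
               tolerance = 1e-6)
})

test_that("regression baseline trains and predicts deterministically", {
  ds <- make_pair_dataset(desk_scene(n_cells = 1L), desk_defocus(),
                          n_pairs = 6, seed = 7)
  m <- train_regression_baseline(ds$pairs, tiny_denoiser(),
                                 diffusion_config(steps = 30L,
                                                  batch_size = 4L,
                                                  learning_rate = 1e-3),
                                 seed = 8)
  expect_lt(mean(tail(m$history, 5)), mean(head(m$history, 5)))
  cond <- ds$pairs[[1]]$oof
  expect_identical(predict_regression(m, cond), predict_regression(m, cond))
})

test_that("degenerate configurations run end-to-end (smoke)", {
  ds <- make_pair_dataset(desk_scene(n_cells = 1L), desk_defocus(),
                          n_pairs = 2, seed = 9)
  sched <- make_schedule(2L)
  m <- train_ddpm(ds$pairs, denoiser_spec(base_channels = 2L, n_layers = 1L),
                  sched, diffusion_config(steps = 2L, batch_size = 1L),
                  seed = 1)
  r <- restore_averaged(m, ds$pairs[[1]]$oof, K = 1L, seed = 1)
  expect_equal(dim(r$mean_image), dim(ds$pairs[[1]]$oof))
})
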