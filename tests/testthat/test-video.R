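test_that("video_spec validates rates and burst lengths", {
  expect_error(video_spec(oof_event_rate = 1.2), "\\[0, 1\\]")
  expect_error(video_spec(oof_burst_len_frames = c(0L, 2L)), ">= 1")
  expect_s3_class(video_spec(), "video_spec")
})

test_that("no-event and saturated limits of the burst process", {
  sp <- desk_scene(n_cells = 1L)
  m <- desk_defocus()
  v0 <- simulate_video(sp, video_spec(n_frames = 6L, oof_event_rate = 0),
                       m, seed = 1)
  expect_true(all(v0$z_trace == 0))
  # observed frames equal truth up to acquisition noise
  for (f in 1:6) {
    expect_lt(max(abs(v0$observed[[f]] - v0$in_focus[[f]])), 0.08)
  }
  v1 <- simulate_video(sp, video_spec(n_frames = 5L, oof_event_rate = 1,
                                      oof_burst_len_frames = c(5L, 5L)),
                       m, seed = 2)
  expect_true(all(v1$z_trace != 0))
  expect_true(all(abs(v1$z_trace) %in% c(5, 10)))
})

test_that("simulated OOF fraction matches a Markov-chain oracle", {
  # brute-force oracle: simulate the burst chain directly, many frames
  oracle_fraction <- function(rate, len_min, len_max, n, seed) {
    set.seed(seed)
    z <- logical(n)
    remaining <- 0L
    for (i in seq_len(n)) {
      if (remaining == 0L && runif(1) < rate) {
        remaining <- sample(seq(len_min, len_max), 1)
      }
      if (remaining > 0L) {
        z[i] <- TRUE
        remaining <- remaining - 1L
      }
    }
    mean(z)
  }
  ref <- mean(vapply(1:40, function(s) {
    oracle_fraction(0.05, 3, 3, 500, s)
  }, numeric(1)))
  # package path: z traces from many short simulated videos
  sp <- desk_scene(n_cells = 0L)
  vs <- video_spec(n_frames = 50L, oof_event_rate = 0.05,
                   oof_burst_len_frames = c(3L, 3L))
  zs <- unlist(lapply(1:40, function(s) {
    simulate_video(sp, vs, desk_defocus(), seed = 100 + s)$z_trace
  }))
  obs <- mean(zs != 0)
  se <- sqrt(ref * (1 - ref) / length(zs)) + 0.01
  expect_lt(abs(obs - ref), 3 * se)
})

test_that("masks track motion within the step bound", {
  vs <- video_spec(n_frames = 8L, motion_step_px = 1.5, oof_event_rate = 0)
  sim <- simulate_video(desk_scene(n_cells = 2L), vs, desk_defocus(), seed = 4)
  centroid <- function(m) {
    w <- which(m, arr.ind = TRUE)
    colMeans(w)
  }
  for (f in 2:8) {
    for (k in 1:2) {
      d <- sqrt(sum((centroid(sim$masks[[f]][[k]]) -
                       centroid(sim$masks[[f - 1]][[k]]))^2))
      expect_lte(d, 1.5 * 3 + 0.5)
    }
  }
})

test_that("simulate_video is deterministic in the seed", {
  vs <- video_spec(n_frames = 4L)
  a <- simulate_video(desk_scene(), vs, desk_defocus(), seed = 9)
  b <- simulate_video(desk_scene(), vs, desk_defocus(), seed = 9)
  expect_identical(a$observed, b$observed)
  expect_identical(a$z_trace, b$z_trace)
})
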