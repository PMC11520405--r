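test_that("blank wells yield no instances", {
  sc <- render_scene(desk_scene(n_cells = 0L), 1)
  m <- segment_cells(sc$image)
  expect_equal(max(m), 0)
  expect_length(attr(m, "areas"), 0)
})

test_that("well-separated cells are found with IoU >= 0.5 against truth", {
  found <- 0L; total <- 0L
  for (seed in 1:5) {
    sc <- render_scene(desk_scene(n_cells = 3L), seed)
    m <- segment_cells(sc$image)
    expect_equal(max(m), 3)
    for (truth in sc$masks) {
      total <- total + 1L
      ious <- vapply(seq_len(max(m)), function(k) {
        inst <- m == k
        sum(inst & truth) / sum(inst | truth)
      }, numeric(1))
      if (max(ious) >= 0.5) found <- found + 1L
    }
  }
  expect_equal(found, total)
})

test_that("segmentation is deterministic", {
  sc <- render_scene(desk_scene(n_cells = 2L), 11)
  expect_identical(segment_cells(sc$image), segment_cells(sc$image))
})

test_that("defocus inflates segmented areas (boundary thickening)", {
  model <- desk_defocus()
  inflated <- c()
  for (seed in 1:5) {
    sc <- render_scene(desk_scene(n_cells = 2L), seed)
    m0 <- segment_cells(sc$image)
    b5 <- apply_defocus(sc$image, 5, model, seed = seed)
    m5 <- segment_cells(b5)
    # match instances to truth by greatest IoU with a 0.1 floor
    match_area <- function(m, truth) {
      if (max(m) == 0) return(NA_real_)
      ious <- vapply(seq_len(max(m)), function(k) {
        inst <- m == k
        sum(inst & truth) / sum(inst | truth)
      }, numeric(1))
      if (max(ious) < 0.1) return(NA_real_)
      sum(m == which.max(ious))
    }
    for (truth in sc$masks) {
      a0 <- match_area(m0, truth)
      a5 <- match_area(m5, truth)
      if (!is.na(a0) && !is.na(a5)) inflated <- c(inflated, a5 >= a0)
    }
  }
  expect_gt(length(inflated), 5)
  expect_true(all(inflated))
  # at dz = 10 the degradation flips into the other documented failure
  # mode: cells wash out below the segmenter's contrast floor and go
  # undetected (missed detection)
  sc <- render_scene(desk_scene(n_cells = 2L), 1)
  m10 <- segment_cells(apply_defocus(sc$image, 10, model, seed = 2))
  expect_lt(max(m10), max(segment_cells(sc$image)))
})

test_that("detect_contacts matches the brute-force dilation oracle", {
  mk <- matrix(0L, 24, 24)
  mk[8:12, 6:10] <- 1L    # instance 1
  mk[8:12, 12:16] <- 2L   # instance 2, 1 px gap
  for (r in c(0, 1, 2)) {
    got <- detect_contacts(mk, touch_radius_px = r)
    want <- oracle_contacts(mk, r)
    expect_identical(unclass(got)[, ], want, label = paste("radius", r))
  }
  got1 <- detect_contacts(mk, 1)
  expect_true(any(got1))
  expect_equal(attr(got1, "pairs")[1, ], c(i = 1L, j = 2L))
  # relabeling invariance
  mk2 <- mk
  mk2[mk == 1L] <- 2L; mk2[mk == 2L] <- 1L
  expect_identical(matrix(detect_contacts(mk2, 1), 24),
                   matrix(got1, 24))
})

test_that("contacts: single instance, separation bound", {
  mk <- matrix(0L, 16, 16)
  mk[4:8, 4:8] <- 1L
  expect_false(any(detect_contacts(mk, 2)))
  # two discs separated by more than 2 * touch_radius cannot touch
  mk[12:14, 12:14] <- 2L  # gap ~3 px diagonal
  expect_false(any(detect_contacts(mk, 1)))
})

test_that("contact_fidelity agrees with direct formulas", {
  withr::local_seed(1)
  a <- matrix(runif(256) > 0.5, 16)
  b <- matrix(runif(256) > 0.5, 16)
  cf <- contact_fidelity(a, b)
  expect_equal(cf$mse, oracle_mse(as.numeric(a), as.numeric(b)))
  expect_equal(cf$pcc, oracle_pcc(as.numeric(a), as.numeric(b)),
               tolerance = 1e-12)
  same <- contact_fidelity(a, a)
  expect_equal(same$pcc, 1)
  expect_equal(same$mse, 0)
  empty <- matrix(FALSE, 16, 16)
  ef <- contact_fidelity(empty, empty)
  expect_true(is.na(ef$pcc))
  expect_equal(ef$mse, 0)
  expect_error(contact_fidelity(a, matrix(FALSE, 4, 4)), "same shape")
})

test_that("count_error arithmetic", {
  ref <- rep(3, 10)
  test <- c(rep(3, 6), rep(2, 4))
  ce <- count_error(as.list(ref), as.list(test))
  expect_equal(ce$sum, 4)
  expect_equal(ce$mean, 0.4)
  zero <- count_error(as.list(ref), as.list(ref))
  expect_true(all(zero$per_frame == 0))
  expect_error(count_error(as.list(ref), as.list(test[1:5])), "equal length")
})
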