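test_that("tenengrad: zero on constants, offset-invariant, blur-monotone", {
  expect_identical(tenengrad(matrix(0.3, 8, 8)), 0)
  withr::local_seed(1)
  img <- random_image(16)
  expect_equal(tenengrad(img + 0.123), tenengrad(img), tolerance = 1e-10)
  sc <- render_scene(desk_scene(), 1)$image
  m <- defocus_model(sigma_per_um = 1, contrast_decay_per_um = 0)
  tg <- vapply(c(0, 1, 2, 4), function(s) {
    tenengrad(apply_defocus(sc, s, m, noise_sigma = 0))
  }, numeric(1))
  expect_true(all(diff(tg) < 0))
  expect_error(tenengrad(matrix(0, 2, 2)), ">= 3x3")
})

test_that("psnr closed forms and shape checking", {
  img <- random_image(8)
  expect_identical(psnr(img, img), Inf)
  expect_equal(psnr(img, pmin(img + 0.1, Inf)), 20, tolerance = 1e-10)
  expect_error(psnr(img, matrix(0, 4, 4)), "same shape")
  expect_lt(psnr(img, img + 0.2), psnr(img, img + 0.1))
})

test_that("pcc: affine invariance, anti-correlation, constant -> NA", {
  withr::local_seed(2)
  J <- random_image(8)
  expect_equal(pcc(J, 2 * J + 0.1), 1, tolerance = 1e-12)
  expect_equal(pcc(J, -J), -1, tolerance = 1e-12)
  expect_true(is.na(pcc(matrix(1, 8, 8), J)))
  expect_equal(pcc(J, J + 0), pcc(J + 0, J))  # symmetry
  J3 <- matrix(1:9 / 9, 3)
  expect_equal(pcc(J3, matrix(9:1 / 9, 3)), -1, tolerance = 1e-12)
})

test_that("edge_pcc uses the reference mask and is not symmetric", {
  expect_true(is.na(edge_pcc(matrix(0.5, 16, 16), random_image(16))))
  sc <- render_scene(desk_scene(), 4)$image
  expect_equal(edge_pcc(sc, sc), 1, tolerance = 1e-12)
  blur <- apply_defocus(sc, 10, desk_defocus(), seed = 1)
  expect_lte(edge_pcc(sc, blur), pcc(sc, blur))
  # asymmetry: mask from the blurred reference differs
  expect_false(isTRUE(all.equal(edge_pcc(sc, blur), edge_pcc(blur, sc))))
})

test_that("metrics match brute-force oracles on random images", {
  withr::local_seed(3)
  p <- edge_params()
  for (i in 1:10) {
    J <- random_image(8)
    K <- random_image(8)
    expect_lt(rel_err(tenengrad(J), oracle_tenengrad(J)), 1e-10)
    expect_lt(rel_err(psnr(J, K), oracle_psnr(J, K)), 1e-10)
    expect_lt(rel_err(pcc(J, K), oracle_pcc(as.vector(J), as.vector(K))),
              1e-10)
    expect_lt(rel_err(edge_pcc(J, K, p), oracle_edge_pcc(J, K, p)), 1e-10)
  }
})

test_that("metrics are invariant to simultaneous identical cropping", {
  sc <- render_scene(desk_scene(), 5)$image
  blur <- apply_defocus(sc, 5, desk_defocus(), seed = 2)
  i <- 10:50
  # interior crop removes border effects identically for both images
  expect_equal(psnr(sc[i, i], blur[i, i]),
               10 * log10(1 / mean((sc[i, i] - blur[i, i])^2)))
  expect_equal(pcc(sc[i, i], blur[i, i]),
               oracle_pcc(as.vector(sc[i, i]), as.vector(blur[i, i])),
               tolerance = 1e-12)
})

test_that("evaluate_pairs summarizes and counts undefined entries", {
  sc1 <- render_scene(desk_scene(), 6)$image
  sc2 <- render_scene(desk_scene(), 7)$image
  ev <- evaluate_pairs(list(sc1, sc2), list(sc1, sc2))
  expect_equal(ev$per_pair$pcc, c(1, 1))
  expect_equal(ev$per_pair$mse, c(0, 0))
  expect_true(all(is.infinite(ev$per_pair$psnr_db)))
  # order-invariance of the summary
  ev2 <- evaluate_pairs(list(sc2, sc1), list(sc2, sc1))
  expect_equal(ev$summary$median, ev2$summary$median)
  # empty input
  ev0 <- evaluate_pairs(list(), list())
  expect_equal(nrow(ev0$per_pair), 0)
  expect_equal(nrow(ev0$summary), 0)
  expect_error(evaluate_pairs(list(sc1), list()), "equal length")
  # undefined pcc counted as excluded
  flat <- matrix(0.5, 64, 64)
  ev3 <- evaluate_pairs(list(flat), list(flat))
  expect_equal(ev3$summary$n_excluded[ev3$summary$metric == "pcc"], 1)
})
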