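test_that("scene_spec validates its invariants", {
  expect_error(scene_spec(image_size_px = 64, pixel_pitch_um = 0.5),
               "well does not fit")
  expect_error(scene_spec(radius_um_range = c(6, 4)), "ordered")
  expect_error(scene_spec(intensity_fg = 1.5), "\\[0, 1\\]")
  expect_s3_class(desk_scene(), "scene_spec")
})

test_that("render_scene is deterministic and an empty scene has no masks", {
  sp <- desk_scene(n_cells = 0L)
  a <- render_scene(sp, 1)
  b <- render_scene(sp, 1)
  expect_identical(a$image, b$image)
  expect_length(a$masks, 0)
  expect_true(all(a$image >= 0 & a$image <= 1))
  c1 <- render_scene(desk_scene(), 1)
  c2 <- render_scene(desk_scene(), 2)
  expect_false(identical(c1$image, c2$image))
})

test_that("rendered cell masks are disjoint with disc-consistent areas", {
  # pi r^2 for r in [4, 6] um at 0.325 um/px, +/-10% rim tolerance
  sp <- scene_spec(image_size_px = 160L, pixel_pitch_um = 0.325,
                   n_cells = 3L, radius_um_range = c(4, 6))
  for (seed in 1:5) {
    sc <- render_scene(sp, seed)
    expect_length(sc$masks, 3)
    overlap <- Reduce(`+`, lapply(sc$masks, function(m) m * 1L))
    expect_lte(max(overlap), 1L)
    for (m in sc$masks) {
      area <- sum(m)
      expect_gte(area, 0.9 * pi * (4 / 0.325)^2)
      expect_lte(area, 1.1 * pi * (6 / 0.325)^2)
    }
  }
})

test_that("placement failure raises an explicit error", {
  sp <- scene_spec(image_size_px = 64L, pixel_pitch_um = 1, n_cells = 12L,
                   radius_um_range = c(8, 9))
  expect_error(render_scene(sp, 1), "non-overlapping")
})

test_that("defocus_sigma is linear, even, and zero at dz = 0", {
  m <- defocus_model(sigma_per_um = 0.8)
  expect_identical(defocus_sigma(0, m), 0)
  expect_equal(defocus_sigma(-10, m), 8)
  expect_equal(defocus_sigma(10, m), defocus_sigma(-10, m))
  expect_equal(defocus_sigma(5, m), defocus_sigma(10, m) / 2)
})

test_that("apply_defocus: identity at dz = 0, degradation otherwise", {
  sc <- render_scene(desk_scene(), 3)
  m <- desk_defocus()
  expect_identical(apply_defocus(sc$image, 0, m, noise_sigma = 0), sc$image)
  b <- apply_defocus(sc$image, 10, m, seed = 1)
  expect_lt(tenengrad(b), tenengrad(sc$image))
  expect_true(all(b >= 0 & b <= 1))
  # same transform under the disk PSF
  md <- defocus_model(psf_family = "disk")
  bd <- apply_defocus(sc$image, 10, md, seed = 1)
  expect_lt(tenengrad(bd), tenengrad(sc$image))
})

test_that("apply_defocus rejects a PSF wider than the image", {
  img <- matrix(0.5, 16, 16)
  m <- defocus_model(sigma_per_um = 2)
  expect_error(apply_defocus(img, 10, m), "larger than image")
})

test_that("tenengrad decreases and PCC-vs-truth does not increase in |dz|", {
  m <- desk_defocus()
  for (seed in 1:4) {
    sc <- render_scene(desk_scene(), seed)
    out <- lapply(c(0, 5, 10), function(dz) {
      apply_defocus(sc$image, dz, m, seed = sub_seed(seed, dz))
    })
    tg <- vapply(out, tenengrad, numeric(1))
    pc <- vapply(out, function(o) pcc(sc$image, o), numeric(1))
    expect_true(all(diff(tg) < 0))
    expect_true(all(diff(pc) <= 0))
  }
})
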