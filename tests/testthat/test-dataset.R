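test_that("make_pair_dataset honors identity fraction and offsets", {
  ds <- make_pair_dataset(desk_scene(), desk_defocus(), n_pairs = 100,
                          identity_fraction = 0.25, offsets_um = 10, seed = 1)
  man <- ds$manifest
  expect_equal(sum(man$is_identity), 25)
  expect_true(all(abs(man$delta_z_um[!man$is_identity]) == 10))
  expect_true(all(man$delta_z_um[man$is_identity] == 0))
  expect_silent(validate_manifest(man))
  # identity pairs are exact copies
  id <- which(man$is_identity)[1]
  expect_identical(ds$pairs[[id]]$in_focus, ds$pairs[[id]]$oof)
  # non-identity pairs differ
  ni <- which(!man$is_identity)[1]
  expect_false(identical(ds$pairs[[ni]]$in_focus, ds$pairs[[ni]]$oof))
})

test_that("identity_fraction = 0 gives only defocused pairs", {
  ds <- make_pair_dataset(desk_scene(), desk_defocus(), n_pairs = 12,
                          identity_fraction = 0, offsets_um = c(5, 10),
                          seed = 2)
  expect_true(all(abs(ds$manifest$delta_z_um) > 0))
  expect_true(all(abs(ds$manifest$delta_z_um) %in% c(5, 10)))
})

test_that("sign of the offset is a fair coin (binomial 99% band)", {
  # n = 40 pairs, offsets {10}: 30 non-identity, signs ~ Binom(30, 0.5)
  counts <- vapply(1:8, function(seed) {
    ds <- make_pair_dataset(desk_scene(n_cells = 0L), desk_defocus(),
                            n_pairs = 40, identity_fraction = 0.25,
                            offsets_um = 10, seed = seed)
    dz <- ds$manifest$delta_z_um
    expect_equal(sum(dz != 0), 30)
    sum(dz > 0)
  }, numeric(1))
  band <- qbinom(c(0.005, 0.995), 30, 0.5)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("manifest validation catches label/offset inconsistency", {
  ds <- make_pair_dataset(desk_scene(n_cells = 1L), desk_defocus(),
                          n_pairs = 10, seed = 3)
  man <- ds$manifest
  bad <- man
  i <- which(bad$focus_label == "oof")[1]
  bad$focus_label[i] <- "in_focus"
  expect_error(validate_manifest(bad), bad$pair_id[i])
})

test_that("dataset round-trips through 16-bit TIFF losslessly", {
  ds <- make_pair_dataset(desk_scene(n_cells = 1L), desk_defocus(),
                          n_pairs = 10, seed = 4)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(nrow(back$manifest), 10)
  # lossless at 16-bit quantization: max error half a quantization step
  q <- 1 / (2^16 - 1)
  for (i in seq_len(10)) {
    expect_lte(max(abs(back$pairs[[i]]$in_focus - ds$pairs[[i]]$in_focus)),
               q / 2 + 1e-12)
    expect_lte(max(abs(back$pairs[[i]]$oof - ds$pairs[[i]]$oof)), q / 2 + 1e-12)
  }
  # a written-then-reread file is bit-stable
  again <- read_dataset(dir)
  expect_identical(back$pairs[[1]]$oof, again$pairs[[1]]$oof)
})

test_that("read_dataset rejects a corrupted manifest", {
  ds <- make_pair_dataset(desk_scene(n_cells = 1L), desk_defocus(),
                          n_pairs = 6, seed = 5)
  dir <- withr::local_tempdir()
  man <- write_dataset(ds, dir)
  i <- which(man$focus_label == "oof")[1]
  man$focus_label[i] <- "in_focus"
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), man$pair_id[i])
})

test_that("make_frame_set composition follows the requested OOF share", {
  fs <- make_frame_set(desk_scene(n_cells = 1L), desk_defocus(), n = 82,
                       seed = 6)
  # default 21:20 OOF:IF
  expect_equal(sum(fs$labels == "oof"), 42)
  expect_true(all((fs$labels == "oof") == (fs$delta_z_um != 0)))
})
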