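test_that("TIFF writer/reader round-trips 8- and 16-bit pages exactly", {
  withr::local_seed(1)
  img <- matrix(round(runif(24 * 17) * 65535) / 65535, 24, 17)
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(img, path, bits = 16L)
  back <- read_tiff(path)
  expect_length(back, 1)
  expect_equal(back[[1]], img, tolerance = 1e-12)
  img8 <- matrix(round(runif(10 * 12) * 255) / 255, 10, 12)
  write_tiff(img8, path, bits = 8L)
  expect_equal(read_tiff(path)[[1]], img8, tolerance = 1e-12)
})

test_that("multi-page stacks preserve page order and content", {
  withr::local_seed(2)
  frames <- lapply(1:5, function(i) matrix(runif(64), 8, 8))
  frames <- lapply(frames, function(f) round(f * 65535) / 65535)
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(frames, path)
  back <- read_tiff(path)
  expect_length(back, 5)
  for (i in 1:5) expect_equal(back[[i]], frames[[i]], tolerance = 1e-12)
})

test_that("python tifffile can read what we write (cross-implementation)", {
  skip_if_not(nzchar(Sys.which("python")))
  img <- matrix(seq(0, 1, length.out = 48), 6, 8)
  img <- round(img * 65535) / 65535
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff(img, path)
  out <- tryCatch(system2("python", c("-c", shQuote(paste0(
    "import tifffile,sys; a=tifffile.imread('", path,
    "'); print(a.shape, a.dtype, a.max())"))),
    stdout = TRUE, stderr = TRUE), error = function(e) NULL)
  skip_if(is.null(out) || length(out) == 0, "python/tifffile unavailable")
  expect_match(paste(out, collapse = " "), "\\(6, 8\\) uint16 65535")
})

test_that("read_image dispatches on extension and rejects unknowns", {
  img <- matrix(0.5, 4, 4)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_tiff(img, path)
  expect_equal(read_image(path), img, tolerance = 1e-4)
  expect_error(read_image("foo.xyz"), "unsupported image format")
})
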