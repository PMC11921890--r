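test_that("cube write/read round-trips across interleaves", {
  set.seed(1)
  cube <- spectral_cube(array(runif(6 * 7 * 101), c(6, 7, 101)))
  td <- withr::local_tempdir()

  # 64-bit storage round-trips doubles bit for bit
  h5 <- file.path(td, "c5.hdr")
  write_cube(cube, h5, data_type = 5L)
  back <- read_cube(h5)
  expect_identical(back$data, cube$data)
  expect_identical(back$wavelengths, cube$wavelengths)

  # all three interleaves of the same cube read back equal
  reads <- lapply(c("bsq", "bil", "bip"), function(il) {
    h <- file.path(td, paste0("c_", il, ".hdr"))
    write_cube(cube, h, interleave = il)
    read_cube(h)$data
  })
  expect_identical(reads[[1]], reads[[2]])
  expect_identical(reads[[1]], reads[[3]])
  # float32 storage is faithful to single precision
  expect_lt(max(abs(reads[[1]] - cube$data)), 1e-6)
})

test_that("cube loading rejects malformed inputs", {
  td <- withr::local_tempdir()
  cube <- spectral_cube(array(0.5, c(4, 4, 101)))
  h <- file.path(td, "c.hdr")
  write_cube(cube, h)

  # header says more bands than the file holds
  txt <- readLines(h)
  writeLines(sub("bands = 101", "bands = 102", txt), h)
  expect_error(read_cube(h), "band count mismatch")

  # no wavelength block
  writeLines(txt[!grepl("wavelength =", txt)], h)
  expect_error(read_cube(h), "no wavelength metadata")

  expect_error(spectral_cube(array(2, c(2, 2, 101))), "outside")
  expect_error(spectral_cube(array(0.5, c(2, 2, 100))), "band count")
  expect_error(spectral_cube(array(NaN, c(2, 2, 101))), "finite")
})

test_that("band_slice snaps wavelengths and matches raw planes", {
  set.seed(2)
  cube <- spectral_cube(array(runif(5 * 5 * 101), c(5, 5, 101)))
  expect_identical(band_slice(cube, 580), cube$data[, , 37])  # (580-400)/5+1
  expect_identical(band_slice(cube, 851), cube$data[, , 91])  # nearest 850
  expect_error(band_slice(cube, 950), "outside")
  # snapping tolerance is half the grid step: a coarse grid exposes it
  coarse <- spectral_cube(array(runif(4 * 4 * 26), c(4, 4, 26)),
                          seq(400, 900, by = 20))
  expect_error(band_slice(coarse, 413), "within")
  # 8-bit export scales to the full range
  s8 <- band_slice(cube, 500, as_8bit = TRUE)
  expect_identical(range(s8), c(0L, 255L))
  expect_identical(band_slice(spectral_cube(array(0.4, c(3, 3, 101))), 500,
                              as_8bit = TRUE), array(0L, c(3, 3)))
})

test_that("label files round-trip and are validated", {
  td <- withr::local_tempdir()
  p <- file.path(td, "l.txt")
  writeLines("0 0.5 0.5 0.2 0.1", p)
  b <- read_labels(p)
  expect_equal(b$class_id, 0L)
  expect_equal(unlist(b[1, 2:5], use.names = FALSE), c(0.5, 0.5, 0.2, 0.1))

  writeLines("3 0.5 0.5 0.2 0.1", p)
  expect_error(read_labels(p, n_classes = 3), "label line 1")
  writeLines(c("0 0.5 0.5 0.2 0.1", "1 1.5 0.5 0.2 0.1"), p)
  expect_error(read_labels(p), "label line 2")

  # round-trip property on random boxes
  set.seed(3)
  boxes <- random_boxes(50)
  write_labels(boxes, p)
  expect_equal(read_labels(p), boxes, tolerance = 1e-9)
})
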