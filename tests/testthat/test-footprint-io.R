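test_that("read_footprint round-trips PNG intensities and handles color", {
  img <- matrix(0, 5, 5)
  img[2:4, 2:4] <- 1
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(img, path)
  gi <- read_footprint(path, resolution = 2)
  expect_equal(sum(gi$pixels == 255), 9)
  expect_equal(sum(gi$pixels == 0), 16)

  # gray RGB image gives the identical luminance grid
  rgb <- array(rep(img, 3), dim = c(5, 5, 3))
  path2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(rgb, path2)
  gi2 <- read_footprint(path2, resolution = 2)
  expect_equal(gi2$pixels, gi$pixels, tolerance = 1e-6)
})

test_that("read_footprint reads TIFF and ascii/binary PGM", {
  img <- matrix(0, 6, 4)
  img[2:5, 2:3] <- 1
  pt <- withr::local_tempfile(fileext = ".tiff")
  tiff::writeTIFF(img, pt)
  expect_equal(sum(read_footprint(pt, resolution = 1)$pixels == 255), 8)

  pg <- withr::local_tempfile(fileext = ".pgm")
  writeLines(c("P2", "# test print", "4 6", "255",
               paste(as.vector(t(img) * 255), collapse = " ")), pg)
  gp <- read_footprint(pg, resolution = 1)
  expect_equal(dim(gp$pixels), c(6, 4))
  expect_equal(sum(gp$pixels == 255), 8)

  pg5 <- withr::local_tempfile(fileext = ".pgm")
  con <- file(pg5, "wb")
  writeChar("P5\n4 6\n255\n", con, eos = NULL)
  writeBin(as.integer(as.vector(t(img) * 255)), con, size = 1)
  close(con)
  expect_equal(read_footprint(pg5, resolution = 1)$pixels, gp$pixels)
})

test_that("read_footprint rejects bad input with informative errors", {
  empty <- withr::local_tempfile(fileext = ".png")
  file.create(empty)
  expect_error(read_footprint(empty, resolution = 2), "empty file")
  expect_error(read_footprint("no/such/file.png", resolution = 2), "not found")
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 3, 3), p)
  cfg <- default_config()
  cfg$resolution_px_per_mm <- NULL
  expect_error(read_footprint(p, config = cfg), "resolution")
})

test_that("binarize thresholds, fills holes, and is idempotent on binary input", {
  px <- matrix(0, 6, 6)
  px[2:5, 2:5] <- 255
  px[3, 3] <- 0  # interior dropout
  fp <- binarize(px, threshold = 128)
  expect_s3_class(fp, "binary_footprint")
  expect_true(fp$mask[3, 3])  # hole filled
  expect_equal(sum(fp$mask), 16)

  # dark-on-light polarity
  fpd <- binarize(255 - px, threshold = 128, polarity = "dark")
  expect_equal(fpd$mask, fp$mask)

  # idempotence: re-thresholding the 0/255 version of the mask changes nothing
  again <- binarize(fp$mask * 255, threshold = 128)
  expect_equal(again$mask, fp$mask)

  expect_error(binarize(matrix(0, 4, 4), threshold = 128), "empty footprint")
})

test_that("binarize removes speck components below min_component_frac", {
  fp0 <- generate_footprint(footprint_params(seed = 2))
  px <- fp0$mask * 255
  px[2, 2:4] <- 255  # 3-pixel speck in a corner
  expect_equal(oracle_n_components(px >= 128), 2)
  fp <- binarize(px, threshold = 128, min_component_frac = 0.01)
  expect_equal(oracle_n_components(fp$mask), 1)
  expect_false(fp$mask[2, 2])
})

test_that("contour of the 3x3 square is the exhaustive 8-pixel cycle", {
  ct <- extract_contour(generate_rectangle(3, 3, pad_px = 2))
  expect_length(ct$components, 1)
  path <- ct$components[[1]]
  expect_equal(nrow(path), 8)
  # closed and 8-connected
  j <- c(2:8, 1)
  steps <- pmax(abs(path[j, 1] - path[, 1]), abs(path[j, 2] - path[, 2]))
  expect_true(all(steps == 1))
})

test_that("degenerate contours: single pixel and two disjoint components", {
  ct <- extract_contour(generate_disk(0.5))
  expect_equal(nrow(ct$components[[1]]), 1)

  m <- matrix(FALSE, 12, 24)
  m[3:5, 3:5] <- TRUE
  m[8:10, 18:20] <- TRUE
  ct2 <- extract_contour(binary_footprint(m))
  expect_length(ct2$components, 2)
})

test_that("traced boundary equals the brute-force 4-neighbor scan", {
  fixtures <- list(
    generate_disk(10)$mask,
    generate_disk(25)$mask,
    generate_rectangle(7, 12)$mask,
    generate_footprint(footprint_params(arch_depth = 0.3, seed = 4))$mask,
    generate_footprint(footprint_params(arch_depth = 0.9, seed = 5,
                                        boundary_noise_px = 1))$mask,
    make_notched_disk()$mask
  )
  for (m in fixtures) {
    ct <- extract_contour(binary_footprint(m))
    expect_setequal(contour_pixel_keys(ct), oracle_boundary_set(m))
    for (path in ct$components) {
      expect_equal(anyDuplicated(paste(path[, 1], path[, 2])), 0)
      if (nrow(path) >= 3) {
        # counterclockwise convention: positive signed area; closed and
        # 8-connected traversal
        expect_gt(footprintr:::signed_area(path), 0)
        j <- c(2:nrow(path), 1)
        cheb <- pmax(abs(path[j, 1] - path[, 1]), abs(path[j, 2] - path[, 2]))
        expect_true(all(cheb == 1))
      }
    }
  }
})
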