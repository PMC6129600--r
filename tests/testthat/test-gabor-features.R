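test_that("gabor kernel has unit center, zero mean, isotropy at epsilon 1", {
  g <- gabor_params()
  raw <- gabor_kernel(g, theta = 0.3, mean_correct = FALSE)
  ctr <- (g$kernel_support_px + 1) / 2
  expect_equal(raw[ctr, ctr], 1 + 0i)
  expect_lt(Mod(sum(gabor_kernel(g, 0.3))), 1e-10)

  giso <- gabor_params(epsilon = 1)
  k0 <- Mod(gabor_kernel(giso, 0, mean_correct = FALSE))
  k90 <- Mod(gabor_kernel(giso, pi / 2, mean_correct = FALSE))
  expect_lt(max(abs(k0 - k90)), 1e-10)
})

test_that("frequency-domain filtering equals direct convolution", {
  direct_conv <- function(img, kern) {
    h <- (nrow(kern) - 1) / 2
    nr <- nrow(img); nc <- ncol(img)
    pad <- matrix(0, nr + 2 * h, nc + 2 * h)
    pad[h + 1:nr, h + 1:nc] <- img
    for (i in 1:h) { pad[i, ] <- pad[h + 1, ]; pad[nr + h + i, ] <- pad[nr + h, ] }
    for (j in 1:h) { pad[, j] <- pad[, h + 1]; pad[, nc + h + j] <- pad[, nc + h] }
    out <- matrix(0, nr, nc)
    kf <- kern[nrow(kern):1, ncol(kern):1]
    for (r in 1:nr) for (c in 1:nc)
      out[r, c] <- sum(pad[r:(r + 2 * h), c:(c + 2 * h)] * kf)
    out
  }
  set.seed(1)
  img <- matrix(runif(20 * 16), 20, 16)
  kern <- Re(gabor_kernel(gabor_params(), 0.7))
  a <- EBImage::filter2(img, kern, boundary = "replicate")
  expect_lt(max(abs(a - direct_conv(img, kern))), 1e-8)
})

test_that("constant images give zero response", {
  w <- wavelet_transform(matrix(1, 40, 40))
  expect_lt(max(w$magnitude), 1e-8)
})

test_that("gratings are assigned the correct dominant orientation", {
  K <- 18
  for (ang in c(30, 80, 120)) {
    fp <- binary_footprint(make_grating(120, 120, ang))
    h <- orientation_histogram(wavelet_transform(fp), fp)
    expected_bin <- floor((ang %% 180) / 10) + 1
    got <- which.max(h)
    circ_dist <- min(abs(got - expected_bin), K - abs(got - expected_bin))
    expect_lte(circ_dist, 1)
  }
})

test_that("transform is translation-invariant and rotation-equivariant", {
  disk <- generate_disk(50)$mask[1:101, 1:101]
  a <- matrix(FALSE, 260, 260); a[30:130, 30:130] <- disk
  b <- matrix(FALSE, 260, 260); b[60:160, 70:170] <- disk
  wa <- wavelet_transform(binary_footprint(a))
  wb <- wavelet_transform(binary_footprint(b))
  expect_lt(max(abs(wa$magnitude[30:130, 30:130] -
                    wb$magnitude[60:160, 70:170])), 1e-6)

  fp <- generate_footprint(footprint_params(arch_depth = 0.5, seed = 5))
  m <- fp$mask
  m90 <- t(m)[, nrow(m):1]
  w1 <- wavelet_transform(binary_footprint(m))
  w2 <- wavelet_transform(binary_footprint(m90))
  mag1r <- t(w1$magnitude)[, nrow(w1$magnitude):1]
  expect_lt(max(abs(mag1r - w2$magnitude)) / max(w2$magnitude), 1e-6)
  # dominant orientation shifts by pi/2 (mod pi) where the response is
  # strong; pixels where two orientations tie to float precision may land in
  # another bin, so the check is distributional
  th1r <- t(w1$dominant_theta)[, nrow(w1$dominant_theta):1]
  strong <- w2$magnitude > 0.5 * max(w2$magnitude)
  shift <- (th1r[strong] + pi / 2) %% pi
  dd <- abs(shift - w2$dominant_theta[strong])
  dd <- pmin(dd, pi - dd)
  expect_gt(mean(dd <= pi / 18 + 1e-9), 0.9)
  expect_equal(median(dd), 0)
})

test_that("second moment obeys its closed forms and homogeneity", {
  fp <- generate_disk(20)
  w <- wavelet_transform(fp)
  expect_gt(second_moment(w, fp), 0)
  wz <- w; wz$magnitude <- w$magnitude * 0
  expect_equal(second_moment(wz, fp), 0)
  wc <- w; wc$magnitude <- w$magnitude * 3
  expect_equal(second_moment(wc, fp), 9 * second_moment(w, fp))
  wm <- w; wm$magnitude[] <- 0.7
  expect_equal(second_moment(wm, fp), 0.49)
})

test_that("orientation histogram normalizes, concentrates, and flattens", {
  K <- 18
  fp <- generate_disk(20)
  w <- wavelet_transform(fp)
  h <- orientation_histogram(w, fp)
  expect_equal(sum(h), 1, tolerance = 1e-12)

  wone <- w
  wone$dominant_theta[] <- 5 * pi / K + 0.01  # inside bin 6
  wone$magnitude[] <- 1
  hone <- orientation_histogram(wone, fp)
  expect_equal(unclass(hone)[6], 1)

  wu <- w
  centers <- (seq_len(K) - 0.5) * pi / K
  wu$dominant_theta[] <- rep_len(centers, length(wu$dominant_theta))
  wu$magnitude[] <- 1
  sel <- matrix(TRUE, nrow(wu$dominant_theta), ncol(wu$dominant_theta))
  hu <- orientation_histogram(wu, binary_footprint(sel))
  expect_true(all(abs(hu - 1 / K) < 1e-3))

  wlow <- w
  wlow$magnitude[] <- 0
  expect_error(orientation_histogram(wlow, fp), "magnitude floor")
  wout <- w
  wout$magnitude[] <- 0
  wout$magnitude[!fp$mask] <- 1  # response only outside the foreground
  expect_error(orientation_histogram(wout, fp), "magnitude floor")
})

test_that("entropy closed forms, bounds, and the isotropic-disk case", {
  expect_equal(orientation_entropy(rep(1 / 18, 18)), log(18))
  expect_equal(orientation_entropy(c(1, rep(0, 9))), 0)
  expect_equal(orientation_entropy(c(0.5, 0.5, rep(0, 6))), log(2))
  # 0 <= E <= ln K for random histograms
  set.seed(7)
  for (i in 1:25) {
    K <- sample(2:24, 1)
    p <- stats::rgamma(K, 0.5); p <- p / sum(p)
    e <- orientation_entropy(p)
    expect_gte(e, 0)
    expect_lte(e, log(K) + 1e-12)
  }
  # a disk has no preferred orientation
  d <- generate_disk(60)
  h <- orientation_histogram(wavelet_transform(d), d)
  expect_rel_error(orientation_entropy(h), log(18), 0.05)
})
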