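# Gabor-wavelet analysis of the print. The filter is a complex exponential
# modulated by an anisotropic Gaussian,
#     psi(x) = exp(i k0 . x) * exp(-1/2 |A x|^2),   A = diag(eps^-1/2, 1),
# so the envelope has standard deviation sqrt(eps) along the filter's
# orientation and 1 across it, and the carrier k0 runs across the
# orientation: the filter at angle theta responds maximally to line-like
# structure oriented at theta. A bank of K orientations theta_k = k*pi/K
# yields, per pixel, the maximal response magnitude and the dominant
# orientation; from these come the second wavelet moment (mean squared
# magnitude over the foreground) and the entropy of the orientation
# histogram, a measure of orientation disorder of the print.

#' Gabor filter-bank parameters
#'
#' @param k0_mag carrier spatial frequency (rad/px); wavelength is
#'   `2*pi/k0_mag` (default wavelength 8 px).
#' @param epsilon envelope anisotropy, >= 1; elongation of the filter along
#'   its orientation (standard deviation `sqrt(epsilon)` px).
#' @param n_orientations number of orientations K spanning `[0, pi)`.
#' @param kernel_support_px odd side length of the kernel; defaults to
#'   covering +/- 3 standard deviations of the envelope.
#' @return a `gabor_params` list.
#' @export
gabor_params <- function(k0_mag = pi / 4, epsilon = 4, n_orientations = 18L,
                         kernel_support_px = NULL) {
  stopifnot(k0_mag > 0, epsilon >= 1, n_orientations >= 2)
  sigma_max <- sqrt(epsilon)
  if (is.null(kernel_support_px))
    kernel_support_px <- 2L * as.integer(ceiling(3 * sigma_max)) + 1L
  kernel_support_px <- as.integer(kernel_support_px)
  if (kernel_support_px %% 2 == 0) kernel_support_px <- kernel_support_px + 1L
  if (kernel_support_px < 2 * 3 * sigma_max)
    warning("kernel support smaller than 3 standard deviations of the envelope")
  structure(list(k0_mag = k0_mag, epsilon = epsilon,
                 n_orientations = as.integer(n_orientations),
                 kernel_support_px = kernel_support_px),
            class = "gabor_params")
}

#' Complex Gabor kernel at one orientation
#'
#' Coordinates are (x = column, y = row). For a pixel offset d, the
#' along-orientation coordinate is `s = dx cos(theta) + dy sin(theta)` and
#' the across coordinate `t = -dx sin(theta) + dy cos(theta)`; the kernel is
#' `exp(i k0 t) * exp(-(s^2/eps + t^2)/2)`, mean-corrected so that constant
#' images give zero response.
#'
#' @param g a [gabor_params()].
#' @param theta orientation in radians.
#' @param mean_correct subtract the kernel mean (default `TRUE`).
#' @return complex matrix of side `g$kernel_support_px`.
#' @export
gabor_kernel <- function(g, theta, mean_correct = TRUE) {
  stopifnot(inherits(g, "gabor_params"))
  h <- (g$kernel_support_px - 1L) %/% 2L
  d <- (-h):h
  dx <- matrix(rep(d, each = length(d)), length(d))   # column offset
  dy <- matrix(rep(d, times = length(d)), length(d))  # row offset
  s <- dx * cos(theta) + dy * sin(theta)
  t <- -dx * sin(theta) + dy * cos(theta)
  psi <- exp(1i * g$k0_mag * t) * exp(-0.5 * (s^2 / g$epsilon + t^2))
  if (mean_correct) psi <- psi - mean(psi)
  psi
}

#' Gabor wavelet transform of a footprint
#'
#' Convolves the 0/1 mask with the kernel at each of the K orientations
#' `theta_k = k*pi/K` (frequency-domain filtering, replicate boundary) and
#' keeps, per pixel, the maximal response magnitude and the orientation
#' attaining it.
#'
#' @param fp a [binary_footprint()] or a numeric matrix (e.g. a grayscale
#'   image) to transform directly.
#' @param g a [gabor_params()].
#' @return object of class `wavelet_response`: list with `magnitude`
#'   (non-negative matrix), `dominant_theta` (matrix, values in `[0, pi)`),
#'   and `params`.
#' @export
wavelet_transform <- function(fp, g = gabor_params()) {
  img <- if (inherits(fp, "binary_footprint")) fp$mask * 1.0 else fp * 1.0
  stopifnot(is.matrix(img))
  K <- g$n_orientations
  mag <- matrix(0, nrow(img), ncol(img))
  th <- matrix(0, nrow(img), ncol(img))
  for (k in 0:(K - 1)) {
    theta <- k * pi / K
    psi <- gabor_kernel(g, theta)
    re <- EBImage::filter2(img, Re(psi), boundary = "replicate")
    im <- EBImage::filter2(img, Im(psi), boundary = "replicate")
    m <- sqrt(re^2 + im^2)
    upd <- m > mag
    mag[upd] <- m[upd]
    th[upd] <- theta
  }
  structure(list(magnitude = mag, dominant_theta = th, params = g),
            class = "wavelet_response")
}

#' Second moment of the wavelet magnitude
#'
#' Raw second moment: the mean of squared response magnitude over the
#' foreground pixels of the print.
#'
#' @param w a `wavelet_response` from [wavelet_transform()].
#' @param fp the [binary_footprint()] defining the foreground.
#' @return non-negative scalar.
#' @export
second_moment <- function(w, fp) {
  stopifnot(inherits(w, "wavelet_response"), inherits(fp, "binary_footprint"))
  mean(w$magnitude[fp$mask]^2)
}

#' Histogram of dominant orientations
#'
#' K equal bins on `[0, pi)` over the foreground pixels whose response
#' magnitude is at least `mag_floor` times the peak magnitude (excluding
#' weak, noise-dominated orientations), normalized to sum to 1.
#'
#' @param w a `wavelet_response`.
#' @param fp the [binary_footprint()] defining the foreground.
#' @param K number of bins; defaults to the bank's `n_orientations`.
#' @param mag_floor fraction of the peak magnitude below which pixels are
#'   excluded (default 0.1).
#' @return object of class `orientation_histogram`: numeric vector `p` of
#'   length K summing to 1, with attribute `breaks`.
#' @export
orientation_histogram <- function(w, fp, K = NULL, mag_floor = 0.1) {
  stopifnot(inherits(w, "wavelet_response"))
  if (is.null(K)) K <- w$params$n_orientations
  stopifnot(K >= 2)
  sel <- if (inherits(fp, "binary_footprint")) fp$mask else fp
  peak <- max(w$magnitude)
  sel <- sel & w$magnitude >= mag_floor * peak
  if (peak == 0 || !any(sel))
    stop("no foreground pixel passes the magnitude floor")
  theta <- w$dominant_theta[sel]
  bin <- pmin(floor(theta / (pi / K)) + 1, K)
  p <- tabulate(bin, nbins = K)
  p <- p / sum(p)
  structure(p, class = "orientation_histogram", K = K)
}

#' Shannon entropy of an orientation histogram
#'
#' `E = -sum(p_i * log(p_i))` in nats, with `0 * log(0)` taken as 0; ranges
#' from 0 (all orientations identical) to `log(K)` (orientation fully
#' disordered).
#'
#' @param h an `orientation_histogram`, or any non-negative vector of bin
#'   frequencies summing to 1.
#' @return entropy in nats.
#' @export
orientation_entropy <- function(h) {
  p <- as.numeric(h)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("not a histogram: frequencies must be non-negative and sum to 1")
  p <- p[p > 0]
  -sum(p * log(p))
}
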