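# Contour curvature and mean bending energy. The local curvature is the
# level-set curvature of a Gaussian-smoothed version f of the mask,
#     k = (2 fx fy fxy - fxx fy^2 - fyy fx^2) / (fx^2 + fy^2)^(3/2),
# with the sign fixed so that a locally convex boundary (e.g. any point of a
# disk) is positive; a straight edge gives 0 and concave indentations (the
# medial arch) give negative values. Partial derivatives are taken with
# Gaussian-derivative filters at scale sigma_px, which regularizes the
# binary step edge. Mean bending energy is the average squared curvature
# along the contour, MBE = (1/N) * sum k(n)^2 — minimal for a circle of the
# same perimeter (1/r^2) and increasingly large for prints with a deep,
# tightly curved medial arch.

gaussian_derivative_kernel <- function(sigma, dx = 0, dy = 0) {
  h <- ceiling(4 * sigma)
  d <- (-h):h
  g <- exp(-d^2 / (2 * sigma^2))
  g <- g / sum(g)
  gd1 <- -d / sigma^2 * g
  gd2 <- (d^2 - sigma^2) / sigma^4 * g
  pick <- function(o) switch(as.character(o), "0" = g, "1" = gd1, "2" = gd2)
  # separable: rows vary with y, columns with x
  outer(pick(dy), pick(dx))
}

#' Level-set curvature field of a footprint mask
#'
#' Smooths the 0/1 mask with a Gaussian of scale `sigma_px` and evaluates
#' the curvature of its level sets from Gaussian-derivative responses.
#' Pixels with a vanishing gradient (`< 1e-6`) are set to 0. On the boundary
#' of a disk of radius r the field is approximately `+1/r`.
#'
#' @param fp a [binary_footprint()].
#' @param sigma_px Gaussian scale in pixels (> 0), default 4.
#' @return numeric matrix of curvature values (1/px).
#' @export
curvature_field <- function(fp, sigma_px = 4) {
  stopifnot(inherits(fp, "binary_footprint"), sigma_px > 0)
  img <- fp$mask * 1.0
  flt <- function(kern) EBImage::filter2(img, kern, boundary = "replicate")
  fx <- flt(gaussian_derivative_kernel(sigma_px, dx = 1))
  fy <- flt(gaussian_derivative_kernel(sigma_px, dy = 1))
  fxx <- flt(gaussian_derivative_kernel(sigma_px, dx = 2))
  fyy <- flt(gaussian_derivative_kernel(sigma_px, dy = 2))
  fxy <- flt(gaussian_derivative_kernel(sigma_px, dx = 1, dy = 1))
  g2 <- fx^2 + fy^2
  k <- (2 * fx * fy * fxy - fxx * fy^2 - fyy * fx^2) / g2^1.5
  k[sqrt(g2) < 1e-6] <- 0
  k
}

#' Curvature sampled along the contour
#'
#' Evaluates the curvature field at every contour pixel; multi-component
#' contours are concatenated, so `N` is the total boundary pixel count.
#'
#' @param fp a [binary_footprint()].
#' @param contour optional precomputed [extract_contour()] result.
#' @param sigma_px Gaussian scale in pixels.
#' @return object of class `curvature_series`: list with `k` (numeric vector
#'   of per-pixel curvature, 1/px), `N`, and `sigma_px`.
#' @export
contour_curvature <- function(fp, contour = NULL, sigma_px = 4) {
  stopifnot(inherits(fp, "binary_footprint"))
  if (is.null(contour)) contour <- extract_contour(fp)
  field <- curvature_field(fp, sigma_px)
  k <- unlist(lapply(contour$components, function(path)
    field[cbind(path[, 1], path[, 2])]), use.names = FALSE)
  stopifnot(length(k) >= 1, all(is.finite(k)))
  structure(list(k = k, N = length(k), sigma_px = sigma_px),
            class = "curvature_series")
}

#' Mean bending energy
#'
#' `MBE = (1/N) * sum k(n)^2` over the contour pixels: the energy needed to
#' bend the outline into a circle of the same perimeter. Units 1/px^2.
#'
#' @param cs a `curvature_series` from [contour_curvature()], or a bare
#'   numeric vector of curvature values.
#' @return non-negative scalar.
#' @export
mean_bending_energy <- function(cs) {
  k <- if (inherits(cs, "curvature_series")) cs$k else cs
  stopifnot(is.numeric(k), length(k) >= 1)
  mean(k^2)
}

#' Mean absolute curvature
#'
#' Scalar curvature summary exported in the feature table: the mean of
#' `|k(n)|` along the contour.
#'
#' @inheritParams mean_bending_energy
#' @return non-negative scalar (1/px).
#' @export
mean_abs_curvature <- function(cs) {
  k <- if (inherits(cs, "curvature_series")) cs$k else cs
  mean(abs(k))
}
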