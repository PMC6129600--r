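# Synthetic toeless plantar prints with a controllable medial-arch
# indentation, plus analytic fixture shapes (disks, rectangles). The foot
# template is a heel disk and a forefoot ellipse joined by a midfoot band
# whose medial edge is carved by an indentation ellipse; arch_depth 0 gives a
# flat (fully filled) print, arch_depth near 1 narrows the band below 10% of
# the foot width. All dimensions are in mm and rasterized at `resolution`
# px/mm, so masks scale consistently with resolution.

#' Parameters of the synthetic footprint generator
#'
#' @param length_mm heel-to-metatarsal length of the toeless print (mm).
#' @param width_mm maximal print width (mm); must be less than `length_mm`.
#' @param arch_depth medial-arch indentation in `[0, 1]`: 0 is a flat foot
#'   (full midfoot contact), values near 1 leave a midfoot strip under 10%
#'   of the width, emulating a severe high arch.
#' @param side `"left"` or `"right"`; sides are exact mirror images for the
#'   same seed.
#' @param resolution pixels per mm.
#' @param boundary_noise_px standard deviation (px) of radial jitter applied
#'   to the outline; 0 disables noise.
#' @param smooth_mm outline rounding scale (mm): the raw template union is
#'   blurred with a Gaussian of this scale and re-thresholded at 0.5, so the
#'   junctions between heel, band and forefoot are rounded the way a real
#'   ink print is; 0 keeps the raw template with its sharp corners.
#' @param seed integer seed making the print reproducible.
#' @return a `footprint_params` list.
#' @export
footprint_params <- function(length_mm = 180, width_mm = 90, arch_depth = 0,
                             side = c("left", "right"), resolution = 2,
                             boundary_noise_px = 0, smooth_mm = 6, seed = 1L) {
  side <- match.arg(side)
  if (!(is.numeric(length_mm) && is.numeric(width_mm) &&
        length_mm > width_mm && width_mm > 0))
    stop("invalid parameters: need length_mm > width_mm > 0")
  if (!is.numeric(arch_depth) || arch_depth < 0 || arch_depth > 1)
    stop("invalid parameters: arch_depth must be in [0, 1]")
  if (resolution <= 0) stop("invalid parameters: resolution must be positive")
  if (boundary_noise_px < 0)
    stop("invalid parameters: boundary_noise_px must be >= 0")
  if (smooth_mm < 0) stop("invalid parameters: smooth_mm must be >= 0")
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 arch_depth = arch_depth, side = side,
                 resolution = resolution,
                 boundary_noise_px = boundary_noise_px,
                 smooth_mm = smooth_mm,
                 seed = as.integer(seed)),
            class = "footprint_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  force(code)
}

#' Generate a synthetic toeless footprint
#'
#' Rasterizes the heel-disk / midfoot-band / forefoot-ellipse template at the
#' requested resolution. The medial band edge is indented by an ellipse whose
#' horizontal semi-axis grows linearly with `arch_depth`, so midfoot contact
#' area is non-increasing in `arch_depth`. Optional boundary noise perturbs
#' the traced outline radially (smoothed Gaussian jitter) before
#' re-rasterization. Deterministic given the seed.
#'
#' @param p a [footprint_params()] object (or arguments passed to it).
#' @param ... convenience: fields of [footprint_params()] if `p` is missing.
#' @return a [binary_footprint()].
#' @export
#' @examples
#' fp <- generate_footprint(footprint_params(arch_depth = 0.5, seed = 42))
#' sum(fp$mask)
generate_footprint <- function(p, ...) {
  if (missing(p)) p <- footprint_params(...)
  stopifnot(inherits(p, "footprint_params"))
  L <- p$length_mm; W <- p$width_mm; res <- p$resolution
  margin <- 6  # mm of background padding
  nr <- round((L + 2 * margin) * res)
  nc <- round((W + 2 * margin) * res)
  # pixel-center coordinates in mm; rows run heel (y = 0) to forefoot (y = L)
  y <- ((1:nr) - 0.5) / res - margin
  x <- ((1:nc) - 0.5) / res - margin
  X <- matrix(rep(x, each = nr), nr, nc)
  Y <- matrix(rep(y, times = nc), nr, nc)

  r_heel <- 0.40 * W
  heel_c <- c(W / 2, r_heel + 0.02 * L)
  fore_ay <- 0.22 * L
  fore_c <- c(W / 2, L - fore_ay)
  heel <- (X - heel_c[1])^2 + (Y - heel_c[2])^2 <= r_heel^2
  fore <- ((X - fore_c[1]) / (W / 2))^2 + ((Y - fore_c[2]) / fore_ay)^2 <= 1
  band <- X >= 0.05 * W & X <= 0.95 * W & Y >= heel_c[2] & Y <= fore_c[2]
  mask <- heel | fore | band
  if (p$arch_depth > 0) {
    # medial indentation: canonical template is a left foot seen from below,
    # medial edge at x = W
    ind_ax <- p$arch_depth * 0.92 * W
    ind_ay <- 0.45 * (fore_c[2] - heel_c[2])
    ind_cy <- (heel_c[2] + fore_c[2]) / 2
    indent <- ((X - W) / ind_ax)^2 + ((Y - ind_cy) / ind_ay)^2 <= 1
    mask <- mask & !indent
  }
  if (p$smooth_mm > 0) {
    mask <- EBImage::gblur(mask * 1.0, sigma = p$smooth_mm * res) > 0.5
  }
  if (p$boundary_noise_px > 0) {
    mask <- with_seed(p$seed, jitter_outline(mask, p$boundary_noise_px))
  }
  if (p$side == "right") mask <- mask[, ncol(mask):1]
  # heel at the bottom of the image, as prints are usually viewed
  mask <- mask[nrow(mask):1, ]
  binary_footprint(mask, resolution = res, side = p$side)
}

# Radial jitter of each contour component: N(0, sd) offsets along the
# outline (lightly averaged over 3 neighbors so the perturbed polygon stays
# simple), re-rasterized by even-odd scanline fill. Rasterization specks and
# pinholes are cleaned up afterwards so the jittered mask still satisfies
# the footprint invariants.
jitter_outline <- function(mask, sd_px) {
  fp <- binary_footprint(mask, resolution = 1)
  ct <- extract_contour(fp)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (path in ct$components) {
    n <- nrow(path)
    if (n < 8) { out[path] <- TRUE; next }
    ctr <- colMeans(path)
    e <- stats::rnorm(n, 0, sd_px)
    e <- stats::filter(rep(e, 3), rep(1 / 3, 3))[(n + 1):(2 * n)]
    d <- sweep(path, 2, ctr)
    rad <- sqrt(rowSums(d^2))
    # the physical boundary runs ~half a pixel outside the boundary-pixel
    # centers; offsetting by +0.5 px puts scanline crossings mid-pixel so the
    # rasterization responds continuously to sub-pixel jitter
    poly <- sweep(d * (1 + (0.5 + e) / pmax(rad, 1e-9)), 2, ctr, "+")
    out <- out | rasterize_polygon(poly, nrow(mask), ncol(mask))
  }
  out <- EBImage::fillHull(out * 1L) > 0
  lab <- EBImage::bwlabel(out * 1L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= 0.01 * sum(sizes))
  matrix(lab %in% keep, nrow(out), ncol(out))
}

# Even-odd scanline rasterization of a closed polygon given as (row, col)
# vertices; pixel centers at integer coordinates.
rasterize_polygon <- function(poly, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  ys <- poly[, 1]; xs <- poly[, 2]
  n <- length(ys)
  j <- c(2:n, 1)
  for (r in max(1, floor(min(ys))):min(nr, ceiling(max(ys)))) {
    y1 <- ys; y2 <- ys[j]
    crosses <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(crosses)) next
    t <- (r - y1[crosses]) / (y2[crosses] - y1[crosses])
    xc <- sort(xs[crosses] + t * (xs[j][crosses] - xs[crosses]))
    for (i in seq(1, length(xc) - 1, by = 2)) {
      c1 <- max(1, ceiling(xc[i])); c2 <- min(nc, floor(xc[i + 1]))
      if (c1 <= c2) out[r, c1:c2] <- TRUE
    }
  }
  out
}

#' Rasterized disk fixture
#'
#' Foreground pixels are those whose center lies within `radius_px` of the
#' canvas center. `radius_px = 0.5` yields a single pixel.
#'
#' @param radius_px disk radius in pixels (>= 0.5).
#' @param resolution pixels per mm (metadata only).
#' @return a [binary_footprint()].
#' @export
generate_disk <- function(radius_px, resolution = 2) {
  stopifnot(radius_px >= 0.5)
  h <- ceiling(radius_px) + 2
  n <- 2 * h + 1
  d <- (1:n) - (h + 1)
  D2 <- outer(d^2, d^2, "+")
  binary_footprint(D2 <= radius_px^2, resolution = resolution)
}

#' Rasterized rectangle fixture
#'
#' A filled `w_px` (columns) by `h_px` (rows) block centered in a padded
#' canvas.
#'
#' @param w_px,h_px width (columns) and height (rows) in pixels, >= 1.
#' @param pad_px background padding on each side.
#' @param resolution pixels per mm (metadata only).
#' @return a [binary_footprint()].
#' @export
generate_rectangle <- function(w_px, h_px, pad_px = 3, resolution = 2) {
  stopifnot(w_px >= 1, h_px >= 1, pad_px >= 0)
  mask <- matrix(FALSE, h_px + 2 * pad_px, w_px + 2 * pad_px)
  mask[pad_px + (1:h_px), pad_px + (1:w_px)] <- TRUE
  binary_footprint(mask, resolution = resolution)
}
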