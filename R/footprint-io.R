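# ---- domain types ----------------------------------------------------------

new_gray_image <- function(pixels, resolution) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            nrow(pixels) >= 1, ncol(pixels) >= 1)
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("configuration error: resolution (px per mm) must be a positive number")
  structure(list(pixels = pixels, resolution = resolution),
            class = "gray_image")
}

#' Construct a binary footprint object
#'
#' A `binary_footprint` is the working representation of a toeless plantar
#' print: a logical mask (`TRUE` = foreground/ink), the spatial resolution in
#' pixels per mm, and which foot it is, if known.
#'
#' @param mask logical matrix, `TRUE` for foreground pixels; at least one.
#' @param resolution pixels per mm (positive scalar).
#' @param side one of `"left"`, `"right"`, `"unknown"`.
#' @return object of class `binary_footprint`.
#' @export
binary_footprint <- function(mask, resolution = 2, side = "unknown") {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty footprint: mask has no foreground pixels")
  side <- match.arg(side, c("left", "right", "unknown"))
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be positive")
  structure(list(mask = mask, resolution = resolution, side = side),
            class = "binary_footprint")
}

#' @export
print.binary_footprint <- function(x, ...) {
  cat(sprintf("<binary_footprint> %d x %d px, %.3g px/mm, side=%s, area=%d px\n",
              nrow(x$mask), ncol(x$mask), x$resolution, x$side, sum(x$mask)))
  invisible(x)
}

# ---- image reading ---------------------------------------------------------

#' Read a footprint image
#'
#' Reads an 8-bit grayscale or RGB image (PNG, TIFF or PGM) into an intensity
#' grid on the 0-255 scale. Color images are converted to luminance
#' (Rec. 709 weights). The spatial resolution must be supplied, either
#' directly or through the configuration.
#'
#' @param path path to a `.png`, `.tif`/`.tiff`, or `.pgm` file.
#' @param resolution pixels per mm; if `NULL`, taken from
#'   `config$resolution_px_per_mm`.
#' @param config configuration list, see [default_config()].
#' @return a `gray_image`: list with `pixels` (matrix, 0-255) and
#'   `resolution`.
#' @export
read_footprint <- function(path, resolution = NULL, config = default_config()) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  if (file.info(path)$size == 0) stop("I/O error: empty file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = tryCatch(png::readPNG(path),
                    error = function(e) stop("I/O error reading ", path, ": ",
                                             conditionMessage(e))),
    tif  = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("I/O error reading ", path, ": ",
                                             conditionMessage(e))),
    pgm  = read_pgm(path),
    stop("I/O error: unsupported image format '", ext, "' for ", path)
  )
  if (ext != "pgm") {
    # png/tiff readers return [0,1]; drop alpha, collapse color to luminance
    if (length(dim(px)) == 3) {
      nc <- dim(px)[3]
      if (nc >= 3) {
        px <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
      } else {
        px <- px[, , 1]
      }
    }
    px <- px * 255
  }
  if (is.null(resolution)) resolution <- config$resolution_px_per_mm
  if (is.null(resolution))
    stop("configuration error: no resolution (px per mm) supplied for ", path)
  new_gray_image(px, resolution)
}

# Minimal PGM (P2 ascii / P5 binary, 8-bit) reader; none of the installed
# image packages handles the netpbm formats.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval, with '#' comments allowed
  while (length(tokens) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || !nzchar(ch)) stop("I/O error: truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (!length(ch) || ch == "\n") break
      }
    } else if (grepl("[[:space:]]", ch)) {
      next
    } else {
      tok <- ch
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (!length(ch) || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5")) stop("I/O error: not an 8-bit PGM: ", path)
  if (is.na(w) || is.na(h) || w < 1 || h < 1)
    stop("I/O error: bad PGM dimensions in ", path)
  vals <- if (magic == "P5") {
    as.numeric(readBin(con, "integer", n = w * h, size = 1, signed = FALSE))
  } else {
    scan(con, what = numeric(), n = w * h, quiet = TRUE)
  }
  if (length(vals) < w * h) stop("I/O error: truncated PGM data in ", path)
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  m * (255 / maxval)
}

# ---- binarization ----------------------------------------------------------

#' Binarize a grayscale footprint image
#'
#' Thresholds the intensity grid into a foreground mask, fills interior
#' holes (ink dropouts), and removes speck components smaller than
#' `min_component_frac` of the total foreground. Severe high-arch prints may
#' legitimately split into separate heel and forefoot regions, so all
#' components above the speck threshold are retained and analysed as a union.
#'
#' @param img a `gray_image` (from [read_footprint()]) or a plain numeric
#'   matrix of intensities in `[0, 255]`.
#' @param threshold intensity cut in `[0, 255]`; foreground is
#'   `>= threshold` for `polarity = "light"`, `<= threshold` for `"dark"`.
#' @param polarity `"light"` (ink brighter than background) or `"dark"`.
#' @param fill_holes fill enclosed background regions (default `TRUE`).
#' @param min_component_frac components below this fraction of total
#'   foreground are dropped.
#' @param resolution pixels per mm, used when `img` is a bare matrix.
#' @param side foot side annotation passed through.
#' @return a [binary_footprint()].
#' @export
binarize <- function(img, threshold = 128, polarity = c("light", "dark"),
                     fill_holes = TRUE, min_component_frac = 0.01,
                     resolution = NULL, side = "unknown") {
  polarity <- match.arg(polarity)
  if (inherits(img, "gray_image")) {
    px <- img$pixels
    if (is.null(resolution)) resolution <- img$resolution
  } else {
    px <- img
  }
  if (is.null(resolution)) resolution <- 2
  stopifnot(is.matrix(px), threshold >= 0, threshold <= 255)
  mask <- if (polarity == "light") px >= threshold else px <= threshold
  if (!any(mask)) stop("empty footprint: no foreground pixels at threshold ",
                       threshold)
  if (fill_holes) {
    mask <- EBImage::fillHull(mask * 1L) > 0
  }
  if (min_component_frac > 0) {
    lab <- EBImage::bwlabel(mask * 1L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_frac * sum(sizes))
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) stop("empty footprint: all components below size threshold")
  binary_footprint(mask, resolution = resolution, side = side)
}

# ---- contour extraction ----------------------------------------------------

# Boundary membership: foreground pixels with at least one background
# 4-neighbor (pixels on the image border count their outside as background).
boundary_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  bg <- !pad
  nb_bg <- bg[1:nr, 2:(nc + 1)] | bg[3:(nr + 2), 2:(nc + 1)] |
           bg[2:(nr + 1), 1:nc] | bg[2:(nr + 1), 3:(nc + 2)]
  mask & nb_bg
}

# Moore-neighbor boundary tracing of one labelled component, returning an
# ordered closed pixel path; offsets in clockwise screen order.
.moore_offsets <- matrix(c(0, 1,  1, 1,  1, 0,  1, -1,
                           0, -1, -1, -1, -1, 0, -1, 1),
                         ncol = 2, byrow = TRUE)

trace_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  # start: first foreground pixel in column-major scan; its W neighbor is bg
  start <- which(pad)[1]
  sr <- (start - 1) %% (nr + 2) + 1
  sc <- (start - 1) %/% (nr + 2) + 1
  off <- .moore_offsets
  off_index <- function(dr, dc) which(off[, 1] == dr & off[, 2] == dc)
  cap <- 4L * sum(mask) + 16L
  path <- matrix(NA_integer_, cap, 2)
  cur <- c(sr, sc)
  # backtrack: the background pixel we arrived from; column-major scan means
  # the pixel above (N) is background
  back <- c(sr - 1L, sc)
  path[1, ] <- cur
  n <- 1L
  # the walk is a deterministic function of the (pixel, backtrack) state, so
  # it terminates exactly when a state repeats (one full boundary cycle)
  seen <- character(0)
  repeat {
    state <- paste(cur[1], cur[2], back[1], back[2])
    if (state %in% seen || n >= cap) break
    seen <- c(seen, state)
    k0 <- off_index(back[1] - cur[1], back[2] - cur[2])
    nxt <- NULL
    for (s in 1:8) {
      k <- (k0 - 1L + s) %% 8L + 1L
      cand <- cur + off[k, ]
      if (pad[cand[1], cand[2]]) {
        nxt <- cand
        prevk <- (k0 - 1L + s - 1L) %% 8L + 1L
        back <- cur + off[prevk, ]
        break
      }
    }
    if (is.null(nxt)) break  # isolated pixel
    n <- n + 1L
    path[n, ] <- nxt
    cur <- nxt
  }
  path <- path[seq_len(n), , drop = FALSE]
  # the final pixel re-enters the cycle; drop trailing duplicate(s) of start
  while (nrow(path) > 1 &&
         all(path[nrow(path), ] == path[1, ])) {
    path <- path[-nrow(path), , drop = FALSE]
  }
  path - 1L  # remove padding offset
}

#' Extract the ordered boundary contour of a footprint
#'
#' Boundary pixels are foreground pixels with at least one background
#' 4-neighbor; each connected component is traced into a closed ordered
#' sequence (Moore-neighbor tracing, so consecutive pixels are 8-adjacent),
#' oriented counterclockwise with foreground on the left (positive signed
#' polygon area in x = column, y = -row coordinates).
#'
#' @param fp a [binary_footprint()].
#' @return object of class `footprint_contour`: list with `components` (list
#'   of n x 2 integer matrices of (row, col), 1-based) and `resolution`.
#' @export
extract_contour <- function(fp) {
  stopifnot(inherits(fp, "binary_footprint"))
  lab <- EBImage::bwlabel(fp$mask * 1L)
  ncomp <- max(lab)
  comps <- vector("list", ncomp)
  for (i in seq_len(ncomp)) {
    cm <- matrix(lab == i, nrow(lab), ncol(lab))
    path <- trace_component(cm)
    bm <- boundary_mask(cm)
    # keep only 4-boundary pixels, drop revisits, preserve cyclic order
    keep <- bm[cbind(path[, 1], path[, 2])]
    path <- path[keep, , drop = FALSE]
    path <- path[!duplicated(path), , drop = FALSE]
    if (nrow(path) >= 3 && signed_area(path) < 0)
      path <- path[nrow(path):1, , drop = FALSE]
    comps[[i]] <- path
  }
  structure(list(components = comps, resolution = fp$resolution),
            class = "footprint_contour")
}

# Shoelace signed area of a pixel path in (x = col, y = -row) coordinates;
# positive for counterclockwise traversal with foreground on the left.
signed_area <- function(path) {
  x <- path[, 2]
  y <- -path[, 1]
  j <- c(2:length(x), 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' @export
print.footprint_contour <- function(x, ...) {
  cat(sprintf("<footprint_contour> %d component(s), %d boundary px total\n",
              length(x$components),
              sum(vapply(x$components, nrow, integer(1)))))
  invisible(x)
}
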