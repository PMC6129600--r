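# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (loops, brute force) and share no code with
# the implementation they check.

# Brute-force boundary scan: foreground pixels with >= 1 background
# 4-neighbor (the image border counts as background).
oracle_boundary_set <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- character(0)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    if (!at(r - 1, c) || !at(r + 1, c) || !at(r, c - 1) || !at(r, c + 1))
      out <- c(out, paste(r, c))
  }
  out
}

# Flood-fill component count (8-connectivity), queue-based.
oracle_n_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    n <- n + 1
    queue <- matrix(c(r0, c0), 1)
    seen[r0, c0] <- TRUE
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  n
}

contour_pixel_keys <- function(ct) {
  unlist(lapply(ct$components, function(p) paste(p[, 1], p[, 2])))
}

# striped binary image whose bars run at `theta_deg` (x = col, y = row),
# period in px
make_grating <- function(nr, nc, theta_deg, period = 16) {
  th <- theta_deg * pi / 180
  r <- matrix(rep(1:nr, times = nc), nr, nc)
  c <- matrix(rep(1:nc, each = nr), nr, nc)
  tcoord <- -c * sin(th) + r * cos(th)
  (tcoord %% period) < period / 2
}

# disk of radius 50 with a 14 px wide, deep slot cut from one side; the slot
# floor is concave boundary
make_notched_disk <- function() {
  d <- generate_disk(50)
  m <- d$mask
  ctr <- (nrow(m) + 1) / 2
  m[(ctr - 7):(ctr + 7), ceiling(ctr + 15):ncol(m)] <- FALSE
  binary_footprint(m)
}

expect_rel_error <- function(measured, expected, tol) {
  expect_lt(abs(measured / expected - 1), tol)
}
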