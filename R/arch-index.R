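# Automated Cavanagh & Rodgers arch index. The toeless print is trisected
# along its longitudinal axis into forefoot (A), midfoot (B) and heel (C)
# sections of equal axial extent, and AI = B / (A + B + C): a flat foot has
# large midfoot contact (high AI), a high arch has little (low AI). The
# longitudinal line is taken as the major principal axis of the foreground
# pixel distribution — the manual heel-to-second-toe line cannot be drawn on
# toeless prints — which makes the index rotation-invariant by construction.

#' Longitudinal axis of a footprint
#'
#' Major principal axis of the foreground pixels, oriented from heel to
#' forefoot using a width heuristic: the end of the print with the smaller
#' local width (the heel is narrower than the ball of the foot) is taken as
#' the heel. Orientation does not affect the arch index itself, only which
#' end is reported as which.
#'
#' @param fp a [binary_footprint()].
#' @return list with `centroid` (row, col), `direction` (unit vector
#'   (row, col) pointing heel to forefoot), and `eigenvalues`.
#' @export
foot_axis <- function(fp) {
  stopifnot(inherits(fp, "binary_footprint"))
  pts <- which(fp$mask, arr.ind = TRUE)
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  S <- crossprod(cc) / nrow(cc)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] <= 0 || e$values[1] / e$values[2] < 1.05)
    stop("no dominant axis: footprint is nearly isotropic")
  u <- e$vectors[, 1]
  proj <- cc %*% u
  perp <- cc %*% e$vectors[, 2]
  ext <- range(proj)
  span <- diff(ext)
  lo <- proj <= ext[1] + 0.2 * span
  hi <- proj >= ext[2] - 0.2 * span
  # heel = narrower end; flip so direction points heel -> forefoot
  if (stats::sd(perp[lo]) > stats::sd(perp[hi])) u <- -u
  list(centroid = ctr, direction = as.numeric(u), eigenvalues = e$values)
}

#' Trisect a footprint along its longitudinal axis
#'
#' Projects every foreground pixel onto the axis, splits the projected
#' extent into three equal intervals, and counts pixels per interval.
#' Sections are labelled A (forefoot), B (midfoot), C (heel). Pixels exactly
#' on a cut line go to the section nearer the heel (deterministic
#' tie-break), and A + B + C equals the total foreground area exactly.
#'
#' @param fp a [binary_footprint()].
#' @param axis result of [foot_axis()]; computed if `NULL`.
#' @return object of class `trisection`: list with `areas` (named A, B, C),
#'   `axis`, and `total`.
#' @export
trisect <- function(fp, axis = NULL) {
  stopifnot(inherits(fp, "binary_footprint"))
  if (is.null(axis)) axis <- foot_axis(fp)
  pts <- which(fp$mask, arr.ind = TRUE)
  proj <- sweep(pts, 2, axis$centroid) %*% axis$direction
  ext <- range(proj)
  cuts <- ext[1] + diff(ext) * c(1, 2) / 3
  # direction points heel -> forefoot: low projections are the heel (C)
  sec <- ifelse(proj <= cuts[1], "C", ifelse(proj <= cuts[2], "B", "A"))
  areas <- c(A = sum(sec == "A"), B = sum(sec == "B"), C = sum(sec == "C"))
  structure(list(areas = areas, axis = axis, total = nrow(pts)),
            class = "trisection")
}

#' Arch index from a trisection
#'
#' `AI = B / (A + B + C)`, the midfoot fraction of total contact area.
#'
#' @param t a `trisection` from [trisect()], or a [binary_footprint()].
#' @return arch index in `[0, 1]`.
#' @export
compute_ai <- function(t) {
  if (inherits(t, "binary_footprint")) t <- trisect(t)
  stopifnot(inherits(t, "trisection"))
  if (t$total <= 0) stop("zero total area")
  unname(t$areas["B"] / sum(t$areas))
}

arch_classification <- function(scheme, score, label) {
  structure(list(scheme = scheme, score = score, label = label),
            class = "arch_classification")
}

#' @export
print.arch_classification <- function(x, ...) {
  cat(sprintf("<arch_classification> scheme=%s score=%.4f label=%s\n",
              x$scheme, x$score, x$label))
  invisible(x)
}

#' Classify an arch index (Cavanagh & Rodgers cut-offs)
#'
#' Low arch for AI >= 0.26, high arch for AI <= 0.21 (both boundaries
#' inclusive), normal in between.
#'
#' @param ai arch index in `[0, 1]`.
#' @return an `arch_classification` with scheme `"cavanagh_rodgers"`.
#' @export
classify_ai <- function(ai) {
  if (!is.numeric(ai) || ai < 0 || ai > 1)
    stop("domain error: arch index must be in [0, 1]")
  label <- if (ai >= 0.26) "low" else if (ai <= 0.21) "high" else "normal"
  arch_classification("cavanagh_rodgers", ai, label)
}
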