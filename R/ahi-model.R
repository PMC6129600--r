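# The arch-height index (AHI) linear model on perimeter and mean bending
# energy,
#     AHI = -7.351e-05 * P - 1050.964 * MBE + 0.4597,
# scaled to mimic the Cavanagh & Rodgers arch index: both coefficients are
# negative, so a longer outline or a more tightly curved (high-arch) outline
# drives the score down. Classification uses the quartile-derived cut-offs
# 0.23 (high arch, inclusive) and 0.27 (low arch, inclusive); the utility
# functions below re-derive cut-offs from a score sample and refit the
# coefficients by ordinary least squares for calibration to a new scanner
# or resolution.

#' Coefficients of the arch-height model
#'
#' Defaults are the published fitted values; `perimeter` multiplies the
#' perimeter in px (boundary-count estimator), `mbe` multiplies the mean bending
#' energy in 1/px^2, both at the 2 px/mm reference scale.
#'
#' @param perimeter,mbe,intercept model coefficients.
#' @return an `ahi_coefficients` list.
#' @export
ahi_coefficients <- function(perimeter = -7.351e-05, mbe = -1050.964,
                             intercept = 0.4597) {
  stopifnot(is.finite(perimeter), is.finite(mbe), is.finite(intercept))
  structure(list(perimeter = perimeter, mbe = mbe, intercept = intercept),
            class = "ahi_coefficients")
}

#' Arch-height score
#'
#' Evaluates the linear model `beta_P * P + beta_MBE * MBE + intercept`.
#' Vectorized over `P` and `mbe`.
#'
#' @param P perimeter in px (>= 0), boundary-count estimator.
#' @param mbe mean bending energy in 1/px^2 (>= 0).
#' @param coeffs an [ahi_coefficients()] object.
#' @return AHI score(s).
#' @export
#' @examples
#' ahi_score(0, 0)          # the model intercept
#' ahi_score(800, 1.2e-4)   # a typical adult print at 2 px/mm
ahi_score <- function(P, mbe, coeffs = ahi_coefficients()) {
  stopifnot(inherits(coeffs, "ahi_coefficients"), all(P >= 0), all(mbe >= 0))
  coeffs$perimeter * P + coeffs$mbe * mbe + coeffs$intercept
}

#' Cut-off scheme for arch classification
#'
#' @param high_max scores `<= high_max` are high arch.
#' @param low_min scores `>= low_min` are low arch.
#' @param name scheme label.
#' @return a `cutoff_scheme` list.
#' @export
cutoff_scheme <- function(high_max = 0.23, low_min = 0.27, name = "mbe_p") {
  if (!(high_max < low_min))
    stop("invalid cut-off scheme: high_max must be below low_min")
  structure(list(high_max = high_max, low_min = low_min, name = name),
            class = "cutoff_scheme")
}

#' Classify an arch-height score
#'
#' Boundaries are inclusive on both sides, mirroring the Cavanagh & Rodgers
#' convention: `ahi <= high_max` is high arch, `ahi >= low_min` low arch,
#' otherwise normal. The default scheme is the quartile-derived 0.23 / 0.27.
#'
#' @param ahi arch-height score (finite).
#' @param scheme a [cutoff_scheme()].
#' @return an `arch_classification`.
#' @export
classify_ahi <- function(ahi, scheme = cutoff_scheme()) {
  stopifnot(is.finite(ahi), inherits(scheme, "cutoff_scheme"))
  label <- if (ahi <= scheme$high_max) "high"
           else if (ahi >= scheme$low_min) "low"
           else "normal"
  arch_classification(scheme$name, ahi, label)
}

#' Derive quartile cut-offs from a score sample
#'
#' First and third quartiles (linear interpolation between order statistics)
#' of the empirical score distribution become the high-arch and low-arch
#' cut-offs: the lowest-scoring quarter of feet is called high arch, the
#' highest-scoring quarter low arch. Reported values are rounded to two
#' decimals; the unrounded quartiles are kept in the scheme.
#'
#' @param scores numeric vector of at least 4 AHI scores.
#' @return a [cutoff_scheme()] with attributes `reported` (2-decimal
#'   rounding) and `n`.
#' @export
derive_quartile_cutoffs <- function(scores) {
  scores <- as.numeric(scores)
  stopifnot(length(scores) >= 4, all(is.finite(scores)))
  if (diff(range(scores)) == 0)
    stop("degenerate scheme: all scores identical")
  q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE, type = 7)
  s <- cutoff_scheme(high_max = q[1], low_min = q[2], name = "quartile")
  attr(s, "reported") <- round(q, 2)
  attr(s, "n") <- length(scores)
  s
}

#' Refit the arch-height model by ordinary least squares
#'
#' Calibration utility: regresses an arch-index target on perimeter and mean
#' bending energy with an intercept. Use it to recalibrate the score to a
#' different scanner resolution or print preparation.
#'
#' @param features data frame with columns `P` (perimeter, px) and `MBE`
#'   (mean bending energy, 1/px^2); at least 3 rows.
#' @param targets numeric response (e.g. Cavanagh & Rodgers arch index), one
#'   per row.
#' @return an [ahi_coefficients()] object with attributes `fit` (the `lm`
#'   object) and `se` (coefficient standard errors).
#' @export
fit_ahi_model <- function(features, targets) {
  stopifnot(is.data.frame(features), all(c("P", "MBE") %in% names(features)))
  if (nrow(features) < 3) stop("fitting error: need at least 3 observations")
  if (length(targets) != nrow(features))
    stop("fitting error: targets length must match feature rows")
  d <- data.frame(AI = targets, P = features$P, MBE = features$MBE)
  fit <- stats::lm(AI ~ P + MBE, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf) || fit$rank < 3)
    stop("fitting error: design matrix is collinear or rank-deficient")
  out <- ahi_coefficients(perimeter = unname(cf["P"]),
                          mbe = unname(cf["MBE"]),
                          intercept = unname(cf["(Intercept)"]))
  attr(out, "fit") <- fit
  attr(out, "se") <- summary(fit)$coefficients[, "Std. Error"]
  out
}
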