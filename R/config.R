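#' Default analysis configuration
#'
#' Returns the full set of tunable parameters used throughout the pipeline,
#' as a nested list. Every key can be overridden via a YAML config file
#' ([read_config()]) or per call.
#'
#' The reference spatial scale is 2 px/mm: the coefficients of the arch-height
#' model ([ahi_score()]) were fitted on scans of that order, and perimeter and
#' bending-energy values only land on the scale the model expects when images
#' are analysed near that resolution.
#'
#' @return Named nested list of configuration values:
#' \describe{
#'   \item{resolution_px_per_mm}{spatial scale of input images (default 2).}
#'   \item{threshold}{binarization threshold on the 0-255 intensity scale.}
#'   \item{polarity}{`"light"` if ink/foreground is brighter than background,
#'     `"dark"` otherwise.}
#'   \item{fill_holes}{fill interior dropouts of the print (default `TRUE`).}
#'   \item{min_component_frac}{foreground components smaller than this
#'     fraction of total foreground are discarded as specks (default 0.01).}
#'   \item{gabor}{`k0_mag` (rad/px), `epsilon` (anisotropy, >= 1),
#'     `n_orientations` (bins on `[0, pi)`), `mag_floor` (fraction of the
#'     peak magnitude below which pixels are excluded from the orientation
#'     histogram).}
#'   \item{curvature}{`sigma_px`: Gaussian scale for the curvature field.}
#'   \item{ahi}{`coefficients` (perimeter, mbe, intercept) and `cutoffs`
#'     (`high_max`, `low_min`) of the arch-height score.}
#' }
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$gabor$n_orientations
default_config <- function() {
  list(
    resolution_px_per_mm = 2,
    threshold = 128,
    polarity = "light",
    fill_holes = TRUE,
    min_component_frac = 0.01,
    gabor = list(
      k0_mag = pi / 4,
      epsilon = 4,
      n_orientations = 18L,
      mag_floor = 0.1
    ),
    curvature = list(sigma_px = 4),
    ahi = list(
      coefficients = list(perimeter = -7.351e-05, mbe = -1050.964,
                          intercept = 0.4597),
      cutoffs = list(high_max = 0.23, low_min = 0.27)
    )
  )
}

#' Read a YAML configuration file
#'
#' Values present in the file override the defaults of [default_config()];
#' everything else keeps its default. Unknown keys are kept (forward
#' compatibility) but unused.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return configuration list as in [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}
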