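# Batch driver: a directory of footprint images in, one CSV row of features
# and classifications per image out. Per-image failures become rows with an
# `error` message rather than aborting the run, matching screening-clinic
# usage where a single smudged print must not sink the batch.

feature_columns <- c("area_px2", "perimeter_px", "circularity",
                     "second_moment", "entropy", "mean_abs_curvature", "mbe",
                     "arch_index", "ahi_score")

#' Full feature vector of one footprint
#'
#' Runs the whole pipeline on a binary print: geometry (area, perimeter with
#' the boundary-count estimator, circularity), Gabor features (second moment,
#' orientation entropy), curvature features (mean absolute curvature, mean
#' bending energy), the Cavanagh & Rodgers arch index with its
#' classification, and the arch-height score with its classification.
#'
#' @param fp a [binary_footprint()].
#' @param config configuration list, see [default_config()].
#' @return named list with the numeric features `area_px2, perimeter_px,
#'   circularity, second_moment, entropy, mean_abs_curvature, mbe,
#'   arch_index, ahi_score` and labels `ai_label, ahi_label`.
#' @export
#' @examples
#' fp <- generate_footprint(footprint_params(arch_depth = 0.5, seed = 3))
#' footprint_features(fp)$arch_index
footprint_features <- function(fp, config = default_config()) {
  stopifnot(inherits(fp, "binary_footprint"))
  ct <- extract_contour(fp)
  A <- footprint_area(fp)
  P <- footprint_perimeter(ct, estimator = "boundary_count")
  g <- gabor_params(k0_mag = config$gabor$k0_mag,
                    epsilon = config$gabor$epsilon,
                    n_orientations = config$gabor$n_orientations)
  w <- wavelet_transform(fp, g)
  hist <- orientation_histogram(w, fp, mag_floor = config$gabor$mag_floor)
  cs <- contour_curvature(fp, ct, sigma_px = config$curvature$sigma_px)
  mbe <- mean_bending_energy(cs)
  ai <- compute_ai(trisect(fp))
  co <- config$ahi$coefficients
  ahi <- ahi_score(P, mbe, ahi_coefficients(co$perimeter, co$mbe, co$intercept))
  cut <- cutoff_scheme(config$ahi$cutoffs$high_max, config$ahi$cutoffs$low_min)
  list(area_px2 = A,
       perimeter_px = P,
       circularity = circularity(P, A),
       second_moment = second_moment(w, fp),
       entropy = orientation_entropy(hist),
       mean_abs_curvature = mean_abs_curvature(cs),
       mbe = mbe,
       arch_index = ai,
       ahi_score = ahi,
       ai_label = classify_ai(ai)$label,
       ahi_label = classify_ahi(ahi, cut)$label)
}

#' Analyse a directory of footprint images
#'
#' Reads every PNG/TIFF/PGM in `input_dir`, binarizes each with the
#' configured threshold and polarity, computes the full feature vector, and
#' writes one CSV row per image, sorted by `image_id` so output does not
#' depend on filesystem enumeration order. Images that fail get a row with
#' `NA` features and the error message in the `error` column; only a batch
#' with no readable image at all is an error.
#'
#' @param input_dir directory containing the images.
#' @param config configuration list or path to a YAML config file.
#' @param output_csv path of the CSV to write, or `NULL` to skip writing.
#' @return the feature table as a data frame, invisibly when written.
#' @export
run_batch <- function(input_dir, config = NULL, output_csv = NULL) {
  if (is.character(config) || is.null(config)) config <- read_config(config)
  files <- list.files(input_dir, pattern = "\\.(png|tif|tiff|pgm)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0)
    stop("no readable images in ", input_dir)
  files <- files[order(basename(files))]
  na_row <- stats::setNames(as.list(rep(NA_real_, length(feature_columns))),
                            feature_columns)
  rows <- lapply(files, function(f) {
    id <- basename(f)
    res <- tryCatch({
      img <- read_footprint(f, config = config)
      fp <- binarize(img, threshold = config$threshold,
                     polarity = config$polarity,
                     fill_holes = config$fill_holes,
                     min_component_frac = config$min_component_frac)
      c(list(image_id = id), footprint_features(fp, config),
        list(error = ""))
    }, error = function(e) {
      message("  [", id, "] failed: ", conditionMessage(e))
      c(list(image_id = id), na_row,
        list(ai_label = NA_character_, ahi_label = NA_character_,
             error = conditionMessage(e)))
    })
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$image_id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(output_csv)) {
    utils::write.csv(out, output_csv, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a set of synthetic fixture prints
#'
#' Generates `n_per_class` prints for each arch-depth stratum (0.1 flat-ish,
#' 0.5 intermediate, 0.9 high arch), writes them as PNG, and records the
#' true generator parameters in `manifest.csv`. Deterministic given `seed`.
#'
#' @param output_dir directory to write into (created if needed).
#' @param n_per_class prints per stratum, >= 1.
#' @param seed integer seed.
#' @param boundary_noise_px passed to the generator; the default 0.5 px
#'   emulates the sub-pixel roughness of a traced-and-scanned outline.
#' @return the manifest data frame, invisibly.
#' @export
make_fixtures <- function(output_dir, n_per_class = 5, seed = 1,
                          boundary_noise_px = 0.5) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("validation error: n_per_class must be >= 1")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) stop("I/O error: cannot create ", output_dir)
  depths <- c(0.1, 0.5, 0.9)
  grid <- expand.grid(idx = seq_len(n_per_class), arch_depth = depths)
  grid$seed <- with_seed(seed, sample.int(1e6, nrow(grid)))
  grid$side <- rep(c("left", "right"), length.out = nrow(grid))
  grid$length_mm <- with_seed(seed + 1,
                              round(stats::rnorm(nrow(grid), 180, 8), 1))
  grid$width_mm <- pmin(round(grid$length_mm * 0.5, 1), 95)
  grid$filename <- sprintf("print_d%02.0f_%02d.png",
                           grid$arch_depth * 100, grid$idx)
  for (i in seq_len(nrow(grid))) {
    p <- footprint_params(length_mm = grid$length_mm[i],
                          width_mm = grid$width_mm[i],
                          arch_depth = grid$arch_depth[i],
                          side = grid$side[i],
                          boundary_noise_px = boundary_noise_px,
                          seed = grid$seed[i])
    fp <- generate_footprint(p)
    png::writePNG(fp$mask * 1, file.path(output_dir, grid$filename[i]))
  }
  manifest <- grid[, c("filename", "arch_depth", "side", "length_mm",
                       "width_mm", "seed")]
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
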