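# Readers and writers for the pipeline artifacts: CSV for tabular data,
# JSON for fit results and run manifests, YAML for configuration files.
# Envelope images are written as CSV matrices (this build carries no
# binary-image dependency).

#' Write a phantom as CSV plus a JSON sidecar
#'
#' Positions and strengths go to `<path>` (columns `x_m`, `y_m`, `z_m`,
#' `strength`); the full [phantom_spec()] including the seed goes to
#' `<path>.json` so the phantom can be rebuilt bit-identically.
#'
#' @param phantom A `phantom`.
#' @param path CSV output path.
#' @return The CSV path, invisibly.
#' @export
write_phantom_csv <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  df <- data.frame(x_m = phantom$positions[, "x"],
                   y_m = phantom$positions[, "y"],
                   z_m = phantom$positions[, "z"],
                   strength = phantom$strengths)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(unclass(phantom$spec), list(n = phantom$n)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom written by [write_phantom_csv()]
#'
#' @param path CSV path (the `.json` sidecar must sit next to it).
#' @return A `phantom`.
#' @export
read_phantom_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- phantom_spec(meta$alpha, meta$rho, meta$cube_side, meta$wavelength,
                       meta$strength_mean, meta$strength_var,
                       meta$hilbert_order, meta$seed)
  pos <- as.matrix(df[, c("x_m", "y_m", "z_m")])
  colnames(pos) <- c("x", "y", "z")
  structure(list(positions = pos, strengths = df$strength, spec = spec,
                 n = nrow(df)),
            class = "phantom")
}

#' Serialize fit results to JSON
#'
#' One record per fit: `model`, `params`, `loglik`, `bic`, `n_iter`,
#' `converged`.
#'
#' @param fits A `fit_result`, a list of them, or a `model_comparison`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fits, path) {
  rec <- function(f) list(model = f$model, params = as.list(f$par),
                          loglik = f$loglik, bic = f$bic, n = f$n,
                          n_iter = f$n_iter, converged = f$converged,
                          method = f$method)
  out <- if (inherits(fits, "fit_result")) rec(fits)
  else if (inherits(fits, "model_comparison"))
    list(fits = lapply(fits$fits, rec), okrr_label = fits$okrr_label,
         rel_diff_pct = fits$rel_diff_pct)
  else lapply(fits, rec)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read amplitudes from a file
#'
#' Accepts a single-column (or headerless) CSV of raw amplitudes, or a
#' histogram CSV with columns `edge_low`, `edge_high`, `count`.
#'
#' @param path Input path.
#' @return Numeric amplitudes or an `amplitude_histogram`.
#' @export
read_amplitudes <- function(path) {
  if (!file.exists(path)) stop("cannot read input file: ", path, call. = FALSE)
  head1 <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(head1) == 0) stop("empty input file: ", path, call. = FALSE)
  if (grepl("edge_low", head1)) return(read_histogram_csv(path))
  has_header <- grepl("[A-Za-z]", head1)
  df <- utils::read.csv(path, header = has_header)
  x <- suppressWarnings(as.numeric(df[[1]]))
  if (length(x) == 0 || all(is.na(x)))
    stop("no numeric amplitudes in: ", path, call. = FALSE)
  check_amplitude(x[!is.na(x)])
}

#' Write an envelope image as CSV
#'
#' Plain matrix CSV (rows = axial samples, columns = lines) with the pixel
#' spacing recorded in a JSON sidecar.
#'
#' @param img An `envelope_image`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_envelope_csv <- function(img, path) {
  stopifnot(inherits(img, "envelope_image"))
  utils::write.table(img$amplitudes, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(axial_step = img$axial_step,
                            lateral_step = img$lateral_step),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the grid outputs
#'
#' `table1_analog.csv` (per-cell parameter and BIC summaries with section
#' labels), `table2_analog.csv` (per-cell SNR) and `manifest.json` (specs
#' and seeds sufficient to re-run bit-identically).
#'
#' @param grid A `grid_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_grid_outputs <- function(grid, dir) {
  stopifnot(inherits(grid, "grid_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(grid$cells, file.path(dir, "table1_analog.csv"),
                   row.names = FALSE)
  utils::write.csv(snr_table(grid), file.path(dir, "table2_analog.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(grid_spec = unclass(grid$spec),
                            acoustic = unclass(grid$acoustic)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reference HK mean-parameter fixture
#'
#' Published per-cell mean HK parameter estimates (`epsilon`, `sigma`, `c`),
#' BIC-based likelihood values and section labels for the 4 x 5
#' (`alpha`, `rho`) organization grid, bundled so the closed-form SNR table
#' can be verified without refitting.
#'
#' @return Data frame with columns `alpha`, `rho`, `epsilon`, `sigma`, `c`,
#'   `L_hk`, `okrr`, `L_okrr`, `section`, `snr_ref`.
#' @export
reference_hk_means <- function() {
  path <- system.file("extdata", "table1_means.csv", package = "hkspeckle")
  utils::read.csv(path, comment.char = "#")
}

#' Read a run configuration from YAML
#'
#' Top-level blocks mirror the constructor argument names
#' (`acoustic`, `grid`, `solver`).
#'
#' @param path YAML file.
#' @return Named list of configuration blocks.
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
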