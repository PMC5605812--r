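# Orchestrated experiments: the (alpha, rho) organization grid with
# repeated realizations (phantom -> envelope -> histogram -> 4 fits ->
# OKRR selection), the closed-form SNR table, and the estimator
# bias / normalized-SD study.

#' Grid specification for the assessment pipeline
#'
#' The full-scale grid covers shape `alpha` in {0.1, 1, 10, 100} and
#' density `rho` in {1, 5, 10, 50, 100} per cubic wavelength with 30
#' realizations and the 12 mm cube; the desk scale (default) reduces this
#' to a 3 x 3 grid, 5 realizations and a 4 mm cube with the scatterer
#' count capped at 2e5.
#'
#' @param alphas Gamma shape values.
#' @param rhos Densities (scatterers per wavelength^3).
#' @param n_realizations Realizations per cell (`>= 2`).
#' @param base_seed Global seed; every stage seed derives from it.
#' @param scale `"desk"` or `"full"`.
#' @return A `grid_spec`.
#' @export
grid_spec <- function(alphas = c(0.1, 1, 100), rhos = c(1, 10, 100),
                      n_realizations = 5L, base_seed = 1L,
                      scale = c("desk", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    if (missing(alphas)) alphas <- c(0.1, 1, 10, 100)
    if (missing(rhos)) rhos <- c(1, 5, 10, 50, 100)
    if (missing(n_realizations)) n_realizations <- 30L
  }
  stopifnot(length(alphas) >= 1, length(rhos) >= 1, n_realizations >= 2)
  structure(list(alphas = alphas, rhos = rhos,
                 n_realizations = as.integer(n_realizations),
                 base_seed = as.integer(base_seed), scale = scale,
                 cube_side = if (scale == "desk") 4e-3 else 12e-3,
                 max_scatterers = if (scale == "desk") 2e5 else Inf),
            class = "grid_spec")
}

# One realization: phantom -> envelope -> central window -> normalized
# histogram of gray levels
simulate_cell_histogram <- function(alpha, rho, cube_side, acoustic, seed,
                                    max_scatterers = Inf, n_bins = 256L) {
  spec <- phantom_spec(alpha, rho, cube_side = cube_side,
                       wavelength = acoustic$wavelength, seed = seed)
  ph <- suppressMessages(build_phantom(spec, max_scatterers = max_scatterers))
  rf <- simulate_rf(ph, acoustic)
  env <- normalize_envelope(detect_envelope(rf))
  amp <- as.vector(envelope_analysis_region(env, cube_side,
                                            decorrelate = TRUE))
  amp <- amp / max(amp)
  amplitude_histogram(amp, n_bins = n_bins)
}

#' Classify a grid cell into the four organization sections
#'
#' Section `*` = clustered/sparse (OKRR = K, no total-reflection flag),
#' `**` = random (Rayleigh), `***` = regular with coherent component
#' (Rician), `****` = total-reflection regime (flagged; by default
#' `alpha >= 1` and `rho >= 50`, a configuration rule rather than simulated
#' physics).
#'
#' @param okrr_label `"K"`, `"RA"` or `"RI"`.
#' @param alpha,rho Cell coordinates.
#' @param total_reflection Logical flag; default from the regime rule.
#' @return One of `"*", "**", "***", "****"`.
#' @export
classify_section <- function(okrr_label, alpha, rho,
                             total_reflection = alpha >= 1 & rho >= 50) {
  okrr_label <- match.arg(okrr_label, c("K", "RA", "RI"))
  if (isTRUE(total_reflection)) return("****")
  switch(okrr_label, K = "*", RA = "**", RI = "***")
}

#' Run the (alpha, rho) assessment grid
#'
#' For every cell and realization: build a phantom, simulate the envelope
#' image, normalize, histogram the gray levels, fit the four models, select
#' the OKRR baseline and compare it with HK. Realizations whose fits fail
#' are excluded (a cell errors when more than 20% are lost). Everything is
#' deterministic from `base_seed`.
#'
#' @param spec A [grid_spec()].
#' @param acoustic An [acoustic_config()].
#' @param cfg A [solver_config()].
#' @return A `grid_result` with `cells` (one summary row per cell: per-model
#'   parameter means and SDs, BIC means and SDs, majority OKRR label,
#'   section, mean relative BIC difference, SNR at the mean HK parameters)
#'   and `realizations` (per-realization detail).
#' @export
run_grid <- function(spec = grid_spec(), acoustic = acoustic_config(),
                     cfg = solver_config()) {
  stopifnot(inherits(spec, "grid_spec"))
  cells <- list()
  reals <- list()
  for (alpha in spec$alphas) for (rho in spec$rhos) {
    per <- list()
    for (r in seq_len(spec$n_realizations)) {
      seed <- derive_seed(spec$base_seed, "grid", alpha, rho, r)
      res <- tryCatch({
        h <- simulate_cell_histogram(alpha, rho, spec$cube_side, acoustic,
                                     seed, spec$max_scatterers)
        cmp <- compare_hk_okrr(h, cfg)
        list(ok = TRUE, cmp = cmp)
      }, error = function(e) list(ok = FALSE, error = conditionMessage(e)))
      per[[r]] <- res
    }
    ok <- vapply(per, function(x) isTRUE(x$ok), TRUE)
    if (mean(!ok) > 0.2)
      stop(sprintf("cell (alpha=%g, rho=%g): %d/%d realizations failed",
                   alpha, rho, sum(!ok), length(ok)), call. = FALSE)
    cmps <- lapply(per[ok], `[[`, "cmp")
    hk_pars <- t(vapply(cmps, function(x) x$hk$par, numeric(3)))
    hk_bic <- vapply(cmps, function(x) x$hk$bic, 0)
    okrr_bic <- vapply(cmps, function(x) x$okrr$bic, 0)
    labels <- vapply(cmps, function(x) x$okrr_label, "")
    maj <- names(sort(table(labels), decreasing = TRUE))[1]
    rd <- vapply(cmps, function(x) x$rel_diff_pct, 0)
    mp <- colMeans(hk_pars)
    cells[[length(cells) + 1L]] <- data.frame(
      alpha = alpha, rho = rho, n_used = sum(ok), n_excluded = sum(!ok),
      eps_mean = mp[["epsilon"]], eps_sd = sd(hk_pars[, "epsilon"]),
      sigma_mean = mp[["sigma"]], sigma_sd = sd(hk_pars[, "sigma"]),
      c_mean = mp[["c"]], c_sd = sd(hk_pars[, "c"]),
      bic_hk_mean = mean(hk_bic), bic_hk_sd = sd(hk_bic),
      bic_okrr_mean = mean(okrr_bic), bic_okrr_sd = sd(okrr_bic),
      okrr_label = maj,
      section = classify_section(maj, alpha, rho),
      rel_diff_pct = mean(rd),
      snr = hk_intensity_snr(mp[["epsilon"]], mp[["sigma"]], mp[["c"]]))
    reals[[sprintf("a%g_r%g", alpha, rho)]] <- cmps
  }
  structure(list(cells = do.call(rbind, cells), realizations = reals,
                 spec = spec, acoustic = acoustic),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid result: %d cells x %d realizations (%s scale)>\n",
              nrow(x$cells), x$spec$n_realizations, x$spec$scale))
  print(x$cells[, c("alpha", "rho", "okrr_label", "section", "c_mean",
                    "rel_diff_pct", "snr")])
  invisible(x)
}

#' Closed-form intensity SNR table
#'
#' Applies [hk_intensity_snr()] per cell. For a `grid_result` the cell
#' means of the fitted HK parameters are used; for a data frame (fixture
#' mode) columns `epsilon`, `sigma`, `c` are used directly, so published
#' mean parameter tables can be verified without refitting.
#'
#' @param x A `grid_result` or a data frame with columns `epsilon`,
#'   `sigma`, `c` (optionally `alpha`, `rho`).
#' @return Data frame with an `snr` column appended.
#' @export
snr_table <- function(x) UseMethod("snr_table")

#' @export
snr_table.grid_result <- function(x) {
  df <- x$cells[, c("alpha", "rho", "eps_mean", "sigma_mean", "c_mean")]
  names(df) <- c("alpha", "rho", "epsilon", "sigma", "c")
  snr_table(df)
}

#' @export
snr_table.data.frame <- function(x) {
  stopifnot(all(c("epsilon", "sigma", "c") %in% names(x)))
  x$snr <- hk_intensity_snr(x$epsilon, x$sigma, x$c)
  x
}

#' Estimator bias and normalized SD study
#'
#' For every `(c, k)` on the grid, draws `n_samples` homodyned-K amplitudes
#' with `epsilon = k * sigma_fixed` and `sigma = sigma_fixed`, fits the HK
#' model by raw-sample MLE, and reports the relative bias
#' `(mean(est) - truth) / truth` and normalized SD `sd(est) / truth` of the
#' clustering degree `c` and of the coherent-to-diffuse ratio
#' `k = epsilon / sigma` over `n_reps` repetitions. `k = 0` is rejected
#' (`epsilon = 0` pins the ratio at an unidentifiable boundary).
#'
#' @param c_set Clustering degrees (positive).
#' @param k_set Coherent-to-diffuse ratios (strictly positive).
#' @param n_samples Draws per repetition (`>= 100`; default 1000).
#' @param n_reps Repetitions per grid point.
#' @param sigma_fixed Diffuse component held fixed (default 1).
#' @param seed Global seed.
#' @param cfg A [solver_config()].
#' @return A `bias_study_result` with a long-format `results` data frame
#'   (`c`, `k`, `bias_c`, `nsd_c`, `bias_k`, `nsd_k`, `n_used`,
#'   `n_excluded`).
#' @export
bias_study <- function(c_set = 1:10, k_set = seq(0.1, 1, by = 0.1),
                       n_samples = 1000L, n_reps = 10L, sigma_fixed = 1,
                       seed = 1L, cfg = solver_config()) {
  stopifnot(length(c_set) >= 1, length(k_set) >= 1, n_samples >= 100,
            n_reps >= 2, sigma_fixed > 0)
  if (any(c_set <= 0)) stop("'c_set' must be positive", call. = FALSE)
  if (any(k_set <= 0))
    stop("'k_set' must be strictly positive: k = 0 makes the ratio epsilon/sigma unidentifiable",
         call. = FALSE)
  rows <- list()
  for (cc in c_set) for (k in k_set) {
    est <- matrix(NA_real_, n_reps, 2)
    conv <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      s <- derive_seed(seed, "bias", cc, k, r)
      a <- speckle_sample("hk",
                          hk_params(k * sigma_fixed, sigma_fixed, cc),
                          n_samples, seed = s)
      f <- fit_mle(a, "hk", cfg)
      conv[r] <- f$converged || f$method == "nelder-mead"
      est[r, ] <- c(f$par[["c"]], f$par[["epsilon"]] / f$par[["sigma"]])
    }
    use <- conv & is.finite(est[, 1])
    rows[[length(rows) + 1L]] <- data.frame(
      c = cc, k = k,
      bias_c = (mean(est[use, 1]) - cc) / cc,
      nsd_c = sd(est[use, 1]) / cc,
      bias_k = (mean(est[use, 2]) - k) / k,
      nsd_k = sd(est[use, 2]) / k,
      n_used = sum(use), n_excluded = sum(!use))
  }
  structure(list(results = do.call(rbind, rows), n_samples = n_samples,
                 n_reps = n_reps, sigma_fixed = sigma_fixed, seed = seed),
            class = "bias_study_result")
}

#' @export
print.bias_study_result <- function(x, ...) {
  cat(sprintf("<bias study: %d grid points, n = %d, %d reps>\n",
              nrow(x$results), x$n_samples, x$n_reps))
  print(x$results, digits = 3)
  invisible(x)
}
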