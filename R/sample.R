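# Random samplers for the four speckle models.
#
# All samplers share the two-quadrature-component construction
# A = sqrt((coh + x)^2 + y^2): the HK model draws the per-component variance
# sigma^2 w with w ~ Gamma(shape c, scale 1); the K model is its eps = 0
# special case; the Rician model fixes w = 1; Rayleigh is Rician with l = 0.

#' Draw amplitudes from a speckle model
#'
#' @param model One of `"rayleigh"`, `"rician"`, `"k"`, `"hk"`.
#' @param params A `speckle_params` object (or named numeric vector) for the
#'   chosen model.
#' @param n Number of i.i.d. draws (`>= 1`).
#' @param seed Optional integer seed; draws are deterministic for a fixed
#'   seed.
#' @return Numeric vector of `n` nonnegative amplitudes.
#' @export
#' @examples
#' a <- speckle_sample("hk", hk_params(0.5, 0.2, 3), n = 1000, seed = 1)
#' mean(a^2)  # ~ epsilon^2 + 2 sigma^2 c = 0.49
speckle_sample <- function(model, params, n, seed = NULL) {
  model <- check_model(model)
  par <- as_par_vector(model, params)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  switch(model,
    rayleigh = {
      d <- par[["d"]]
      sqrt(rnorm(n, 0, d)^2 + rnorm(n, 0, d)^2)
    },
    rician = {
      l <- par[["l"]]; g <- par[["g"]]
      sqrt((l + rnorm(n, 0, g))^2 + rnorm(n, 0, g)^2)
    },
    k = {
      # eps = 0 homodyned-K with c = m, per-component sigma0 = sqrt(2)/a
      m <- par[["m"]]; s0 <- sqrt(2) / par[["a"]]
      w <- rgamma(n, shape = m, scale = 1)
      sd_ <- s0 * sqrt(w)
      sqrt(rnorm(n, 0, sd_)^2 + rnorm(n, 0, sd_)^2)
    },
    hk = {
      eps <- par[["epsilon"]]; s <- par[["sigma"]]; cc <- par[["c"]]
      w <- rgamma(n, shape = cc, scale = 1)
      sd_ <- s * sqrt(w)
      sqrt((eps + rnorm(n, 0, sd_))^2 + rnorm(n, 0, sd_)^2)
    })
}

# Numeric CDF of any of the four models on a grid, for KS-style checks.
# Trapezoidal integration of the density on a fine grid up to a quantile
# bound derived from the model's intensity scale.
speckle_cdf_fun <- function(model, params, n_grid = 4096) {
  par <- as_par_vector(check_model(model), params)
  amax <- switch(model,
    rayleigh = par[["d"]] * sqrt(2 * qgamma(1 - 1e-12, 1)),
    rician = par[["l"]] + par[["g"]] * sqrt(2 * qgamma(1 - 1e-12, 1)),
    k = sqrt(2) / par[["a"]] * sqrt(2 * qgamma(1 - 1e-9, par[["m"]]) *
                                      qgamma(1 - 1e-9, 1)),
    hk = par[["epsilon"]] + par[["sigma"]] *
      sqrt(2 * qgamma(1 - 1e-9, par[["c"]]) * qgamma(1 - 1e-9, 1)))
  a <- seq(0, amax, length.out = n_grid)
  d <- exp(speckle_log_pdf(a, model, par))
  cdf <- cumsum((d[-1] + d[-n_grid]) / 2 * diff(a))
  cdf <- c(0, cdf) / max(cdf[n_grid - 1], 1)
  f <- approxfun(a, pmin(cdf, 1), yleft = 0, yright = 1)
  f
}
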