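# Parameter containers for the four speckle models.
#
# Each constructor validates its invariants and returns a light S3 object;
# the internal .model_info registry drives generic fitting code.

.model_info <- list(
  rayleigh = list(npar = 1L, par_names = "d",
                  lower = c(d = 1e-3), upper = c(d = 10)),
  rician   = list(npar = 2L, par_names = c("l", "g"),
                  lower = c(l = 0, g = 1e-3), upper = c(l = 10, g = 10)),
  k        = list(npar = 2L, par_names = c("m", "a"),
                  lower = c(m = 0.05, a = 0.1), upper = c(m = 500, a = 1000)),
  hk       = list(npar = 3L, par_names = c("epsilon", "sigma", "c"),
                  lower = c(epsilon = 0.01, sigma = 1e-3, c = 1),
                  upper = c(epsilon = 10, sigma = 10, c = 100))
)

.speckle_models <- names(.model_info)

check_model <- function(model) {
  model <- match.arg(model, .speckle_models)
  model
}

new_params <- function(model, par) {
  info <- .model_info[[model]]
  names(par) <- info$par_names
  structure(list(model = model, par = par),
            class = c(paste0(model, "_params"), "speckle_params"))
}

#' Rayleigh model parameters
#'
#' @param d Positive scale; `d^2` is the variance of scatterer strength.
#' @return A `speckle_params` object.
#' @export
#' @examples
#' rayleigh_params(d = 0.3)
rayleigh_params <- function(d) {
  stopifnot(is.numeric(d), length(d) == 1, is.finite(d))
  if (d <= 0) stop("Rayleigh scale 'd' must be > 0", call. = FALSE)
  new_params("rayleigh", c(d = as.numeric(d)))
}

#' Rician model parameters
#'
#' @param l Nonnegative coherent level (mean of scatterer strength).
#' @param g Positive diffuse scale (standard-deviation scale of strength).
#' @return A `speckle_params` object.
#' @export
rician_params <- function(l, g) {
  stopifnot(is.numeric(l), is.numeric(g), length(l) == 1, length(g) == 1,
            is.finite(l), is.finite(g))
  if (l < 0) stop("Rician coherent level 'l' must be >= 0", call. = FALSE)
  if (g <= 0) stop("Rician scale 'g' must be > 0", call. = FALSE)
  new_params("rician", c(l = as.numeric(l), g = as.numeric(g)))
}

#' K model parameters
#'
#' @param m Positive shape (effective scatterer number per resolution cell).
#' @param a Positive scale; `a = 2 * sqrt(m / (2 * sigma^2))` where
#'   `2 * sigma^2` is the second moment of the amplitude.
#' @return A `speckle_params` object.
#' @export
k_params <- function(m, a) {
  stopifnot(is.numeric(m), is.numeric(a), length(m) == 1, length(a) == 1,
            is.finite(m), is.finite(a))
  if (m <= 0) stop("K shape 'm' must be > 0", call. = FALSE)
  if (a <= 0) stop("K scale 'a' must be > 0", call. = FALSE)
  new_params("k", c(m = as.numeric(m), a = as.numeric(a)))
}

#' Homodyned-K model parameters
#'
#' @param epsilon Nonnegative coherent component.
#' @param sigma Positive diffuse component.
#' @param c Positive scatterer clustering degree.
#' @return A `speckle_params` object.
#' @export
#' @examples
#' hk_params(epsilon = 0.36, sigma = 0.16, c = 5.61)
hk_params <- function(epsilon, sigma, c) {
  stopifnot(is.numeric(epsilon), is.numeric(sigma), is.numeric(c),
            length(epsilon) == 1, length(sigma) == 1, length(c) == 1,
            is.finite(epsilon), is.finite(sigma), is.finite(c))
  if (epsilon < 0) stop("HK coherent component 'epsilon' must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("HK diffuse component 'sigma' must be > 0", call. = FALSE)
  if (c <= 0) stop("HK clustering degree 'c' must be > 0", call. = FALSE)
  new_params("hk", c(epsilon = as.numeric(epsilon), sigma = as.numeric(sigma),
                     c = as.numeric(c)))
}

# Coerce a named/unnamed numeric vector or speckle_params to a checked par vector
as_par_vector <- function(model, p) {
  info <- .model_info[[model]]
  if (inherits(p, "speckle_params")) {
    if (p$model != model)
      stop(sprintf("expected %s parameters, got %s", model, p$model), call. = FALSE)
    return(p$par)
  }
  if (!is.numeric(p) || length(p) != info$npar)
    stop(sprintf("model '%s' needs %d parameters (%s)", model, info$npar,
                 paste(info$par_names, collapse = ", ")), call. = FALSE)
  par <- as.numeric(p)
  names(par) <- info$par_names
  # run through constructors for validation
  switch(model,
    rayleigh = rayleigh_params(par[["d"]]),
    rician = rician_params(par[["l"]], par[["g"]]),
    k = k_params(par[["m"]], par[["a"]]),
    hk = hk_params(par[["epsilon"]], par[["sigma"]], par[["c"]]))$par
}

#' @export
print.speckle_params <- function(x, ...) {
  cat(sprintf("<%s speckle model parameters>\n", x$model))
  print(signif(x$par, 6))
  invisible(x)
}
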