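#' Log-likelihood of a speckle model
#'
#' For raw amplitudes returns `sum(log P(x_i))`; for an
#' [amplitude_histogram()] returns the weighted-binned form
#' `sum_b counts_b * log P(center_b)`, the quantity the histogram-based
#' pipeline maximizes. Densities are floored at `1e-300` so the value is
#' always finite.
#'
#' @param data Numeric vector of amplitudes or an `amplitude_histogram`.
#' @param model One of `"rayleigh"`, `"rician"`, `"k"`, `"hk"`.
#' @param params `speckle_params` or numeric parameter vector.
#' @return The log-likelihood (finite scalar).
#' @export
#' @examples
#' log_likelihood(1, "rayleigh", rayleigh_params(1))  # -0.5
log_likelihood <- function(data, model, params) {
  model <- check_model(model)
  par <- as_par_vector(model, params)
  if (inherits(data, "amplitude_histogram")) {
    if (data$n_total == 0) stop("empty histogram", call. = FALSE)
    keep <- data$counts > 0
    a <- hist_centers(data)[keep]
    w <- data$counts[keep]
  } else {
    a <- check_amplitude(data)
    if (length(a) == 0) stop("empty data", call. = FALSE)
    w <- rep(1, length(a))
  }
  lp <- pmax(speckle_log_pdf(a, model, par), log(1e-300))
  sum(w * lp)
}

#' Bayesian information criterion
#'
#' `BIC = -2 * loglik + m * log(n)` with `m` free parameters and `n` data
#' samples; lower is better when comparing models of different complexity.
#'
#' @param loglik Maximized log-likelihood.
#' @param m_params Number of free parameters (`>= 0`).
#' @param n Number of data samples (`>= 1`).
#' @return The BIC value.
#' @export
#' @examples
#' bic_value(-50, 2, 100)
bic_value <- function(loglik, m_params, n) {
  stopifnot(is.numeric(loglik), length(loglik) == 1,
            m_params >= 0, m_params == round(m_params), n >= 1)
  -2 * loglik + m_params * log(n)
}
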