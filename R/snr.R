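#' Closed-form intensity SNR of the homodyned-K model
#'
#' Signal-to-noise ratio of the intensity `I = A^2` under the homodyned-K
#' model, `SNR = E(I) / sd(I)`. With the compound representation
#' (`w ~ Gamma(c, 1)`, per-component variance `sigma^2 w`, coherent level
#' `epsilon`) the mean intensity is `epsilon^2 + 2 sigma^2 c` and its
#' standard deviation `2 sigma sqrt(epsilon^2 c + 2 sigma^2 c + c^2 sigma^2)`,
#' giving
#' `SNR = (epsilon^2 + 2 sigma^2 c) / (2 sigma sqrt(epsilon^2 c + 2 sigma^2 c + c^2 sigma^2))`.
#' For `epsilon = 0`, `c -> Inf` the value tends to 1, the fully developed
#' (Rayleigh) speckle intensity SNR.
#'
#' @param epsilon Nonnegative coherent component.
#' @param sigma Positive diffuse component.
#' @param c Positive clustering degree.
#' @return The intensity SNR (positive scalar, vectorized over inputs).
#' @export
#' @examples
#' hk_intensity_snr(epsilon = 0.36, sigma = 0.16, c = 5.61)  # ~0.97
hk_intensity_snr <- function(epsilon, sigma, c) {
  n <- max(length(epsilon), length(sigma), length(c))
  epsilon <- rep_len(epsilon, n); sigma <- rep_len(sigma, n); c <- rep_len(c, n)
  for (i in seq_len(n)) hk_params(epsilon[i], sigma[i], c[i])
  (epsilon^2 + 2 * sigma^2 * c) /
    (2 * sigma * sqrt(epsilon^2 * c + 2 * sigma^2 * c + c^2 * sigma^2))
}
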