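#' Derive a stage seed from a global seed
#'
#' Every stochastic stage of the pipeline derives its own seed
#' deterministically from the global seed plus a stage label and indices, so
#' a whole run is reproducible from a single integer while stages stay
#' statistically decoupled.
#'
#' @param seed Global integer seed.
#' @param ... Stage label and indices (coerced to character).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "phantom", 0.1, 5, 3)
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}
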