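# Binned envelope amplitudes: the object the pipeline's MLE runs on.

#' Build or validate an amplitude histogram
#'
#' Either bins raw amplitudes (`x`) into `n_bins` equal-width bins over
#' `range`, or wraps pre-computed bin `edges` and `counts`. The pipeline
#' default is 256 equal-width bins over the normalized gray-level range
#' `[0, 1]`.
#'
#' @param x Raw nonnegative amplitudes (ignored when `edges`/`counts` given).
#' @param n_bins Number of equal-width bins (default 256).
#' @param range Binning range, default `c(0, 1)`.
#' @param edges Strictly increasing bin boundaries (length `n_bins + 1`).
#' @param counts Nonnegative integer counts per bin.
#' @return An `amplitude_histogram` with fields `edges`, `counts`,
#'   `n_total`.
#' @export
#' @examples
#' h <- amplitude_histogram(runif(100), n_bins = 32)
#' sum(h$counts) == h$n_total
amplitude_histogram <- function(x = NULL, n_bins = 256L, range = c(0, 1),
                                edges = NULL, counts = NULL) {
  if (is.null(edges)) {
    x <- check_amplitude(x)
    if (length(x) == 0) stop("no amplitudes to bin", call. = FALSE)
    edges <- seq(range[1], range[2], length.out = n_bins + 1L)
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(idx, nbins = n_bins)
  } else {
    if (is.null(counts)) stop("'counts' required with 'edges'", call. = FALSE)
    if (any(diff(edges) <= 0)) stop("'edges' must be strictly increasing", call. = FALSE)
    if (edges[1] < 0) stop("'edges' must start at >= 0", call. = FALSE)
    if (length(counts) != length(edges) - 1L)
      stop("length(counts) must equal length(edges) - 1", call. = FALSE)
    if (any(counts < 0) || any(counts != round(counts)))
      stop("'counts' must be nonnegative integers", call. = FALSE)
  }
  structure(list(edges = as.numeric(edges), counts = as.numeric(counts),
                 n_total = sum(counts)),
            class = "amplitude_histogram")
}

#' @export
print.amplitude_histogram <- function(x, ...) {
  cat(sprintf("<amplitude histogram: %d bins on [%g, %g], n = %d>\n",
              length(x$counts), x$edges[1], x$edges[length(x$edges)],
              as.integer(x$n_total)))
  invisible(x)
}

hist_centers <- function(h) (h$edges[-1] + h$edges[-length(h$edges)]) / 2

#' Write / read an amplitude histogram as CSV
#'
#' Columns `edge_low`, `edge_high`, `count`; lossless round trip.
#'
#' @param h An `amplitude_histogram`.
#' @param path File path.
#' @return `read_histogram_csv` returns an `amplitude_histogram`.
#' @export
write_histogram_csv <- function(h, path) {
  stopifnot(inherits(h, "amplitude_histogram"))
  df <- data.frame(edge_low = h$edges[-length(h$edges)],
                   edge_high = h$edges[-1], count = h$counts)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path)
  amplitude_histogram(edges = c(df$edge_low, df$edge_high[nrow(df)]),
                      counts = df$count)
}
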