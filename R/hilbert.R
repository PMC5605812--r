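# Hilbert space-filling curve vertices, vectorized over curve indices.
#
# Uses the transposed Gray-code formulation (Skilling's algorithm): the
# curve index's bits are distributed round-robin over the dimensions
# ("transpose" form) and then decoded to axis coordinates with bitwise
# operations, all vectorized over an integer vector of indices.

# indices: 0-based curve positions in [0, 2^(order*dim) - 1]
# returns matrix length(indices) x dim of integer coords in [0, 2^order - 1]
hilbert_coords <- function(indices, order, dim) {
  stopifnot(order >= 1, dim %in% c(2L, 3L))
  nbits <- order * dim
  if (nbits > 30) stop("order * dim must be <= 30 (32-bit indices)", call. = FALSE)
  idx <- as.integer(indices)
  if (any(idx < 0 | idx >= 2^nbits)) stop("curve index out of range", call. = FALSE)
  n <- length(idx)
  X <- matrix(0L, n, dim)
  # distribute index bits MSB-first across dimensions
  for (k in 0:(nbits - 1)) {
    bit <- bitwAnd(bitwShiftR(idx, nbits - 1 - k), 1L)
    j <- k %% dim + 1L
    X[, j] <- bitwOr(bitwShiftL(X[, j], 1L), bit)
  }
  # Gray decode
  t <- bitwShiftR(X[, dim], 1L)
  if (dim > 1) for (i in dim:2) X[, i] <- bitwXor(X[, i], X[, i - 1])
  X[, 1] <- bitwXor(X[, 1], t)
  # undo excess work
  Q <- 2L
  N <- bitwShiftL(2L, order - 1L)
  while (Q != N) {
    P <- Q - 1L
    for (i in dim:1) {
      hasQ <- bitwAnd(X[, i], Q) != 0L
      X[hasQ, 1] <- bitwXor(X[hasQ, 1], P)
      tt <- bitwAnd(bitwXor(X[!hasQ, 1], X[!hasQ, i]), P)
      X[!hasQ, 1] <- bitwXor(X[!hasQ, 1], tt)
      X[!hasQ, i] <- bitwXor(X[!hasQ, i], tt)
    }
    Q <- bitwShiftL(Q, 1L)
  }
  X
}

#' Vertices of the Hilbert curve
#'
#' All `2^(order * dim)` vertices of the order-`order` Hilbert curve in
#' `dim` dimensions, in traversal order. Consecutive vertices differ by
#' exactly one unit in exactly one coordinate.
#'
#' @param order Curve order (`>= 1`).
#' @param dim 2 or 3.
#' @return Integer matrix `2^(order*dim) x dim`, coordinates in
#'   `[0, 2^order - 1]`.
#' @export
#' @examples
#' hilbert_vertices(1, 2)  # the 4 corners of the unit square cell
hilbert_vertices <- function(order, dim) {
  hilbert_coords(0:(2^(order * dim) - 1), order, dim)
}

#' Map 1D positions onto the Hilbert curve by arc length
#'
#' The curve's vertices are joined by equal-length segments filling
#' `[0, side]^dim`; a 1D position a fraction `t` along the total curve
#' length is linearly interpolated inside its segment, so nearby 1D
#' positions map to nearby points in space (locality preservation). Vertex
#' coordinates are placed at cell centers, `(X + 0.5) * side / 2^order`.
#' Positions beyond the total curve length are wrapped modulo the length
#' (reported via a message).
#'
#' @param positions Nonnegative 1D positions (same length unit as `side`).
#' @param order Curve order.
#' @param dim 2 or 3.
#' @param side Edge length of the target square/cube.
#' @return Numeric matrix `length(positions) x dim` of coordinates in
#'   `[0, side]^dim`.
#' @export
hilbert_map <- function(positions, order, dim, side) {
  stopifnot(is.numeric(positions), all(positions >= 0), side > 0)
  n_seg <- 2^(order * dim) - 1
  seg_len <- side / 2^order
  total <- n_seg * seg_len
  over <- positions >= total
  if (any(over)) {
    message(sprintf("hilbert_map: %d position(s) beyond curve length wrapped",
                    sum(over)))
    positions <- positions %% total
  }
  s <- positions / seg_len
  k <- pmin(floor(s), n_seg - 1)
  frac <- s - k
  scale <- side / 2^order
  V0 <- (hilbert_coords(k, order, dim) + 0.5) * scale
  V1 <- (hilbert_coords(k + 1, order, dim) + 0.5) * scale
  V0 + frac * (V1 - V0)
}
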