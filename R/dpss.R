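#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the eigenvectors of the standard symmetric tridiagonal
#' commuting matrix. Tapers are returned as columns, normalized to unit
#' energy (`colSums(v^2) == 1`) and sign-fixed so that symmetric tapers have
#' positive mean and antisymmetric tapers positive initial slope.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (e.g. 3).
#' @param k number of tapers to return (at most `2*nw - 1` is advisable).
#' @return an `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- paste(n, nw, k, sep = "_")
  cached <- .spikefield_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  t <- seq_len(n) - 1
  diagonal <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  offdiag <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  # dense symmetric matrix: n is small (<= a few thousand) in practice
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diagonal
  A[cbind(seq_len(n - 1), seq(2, n))] <- offdiag
  A[cbind(seq(2, n), seq_len(n - 1))] <- offdiag
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  for (j in seq_len(k)) {
    if (j %% 2 == 1) {
      if (sum(v[, j]) < 0) v[, j] <- -v[, j]
    } else {
      slope <- sum((t - (n - 1) / 2) * v[, j])
      if (slope < 0) v[, j] <- -v[, j]
    }
  }
  .spikefield_cache[[key]] <- v
  v
}

.spikefield_cache <- new.env(parent = emptyenv())
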