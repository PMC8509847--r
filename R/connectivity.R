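#' Per-band functional connectivity
#'
#' Pearson correlation between every pair of region band series, computed
#' over retained volumes only (pairwise deletion applies the scrub mask here,
#' after filtering, so the wavelet transform always sees a contiguous
#' series). For 76 regions the matrix carries the 2850 unique connections of
#' a frequency-specific undirected graph.
#'
#' Regions with zero variance over the retained volumes get correlation 0
#' with a warning rather than \code{NA}: a zero never survives
#' positive-weight density thresholding, so downstream topology stays total.
#' No Fisher z-transform is applied anywhere; all downstream comparisons and
#' thresholding operate on raw r.
#'
#' @param bands a [BandSet-class].
#' @param bandIndex which detail level to correlate (1 = finest).
#' @param scrubMask optional logical retained-volume vector; defaults to the
#'   mask carried by \code{bands} (all volumes when absent).
#' @param subjectId,session provenance labels stored in the result.
#' @param minVolumes minimum retained volumes required (default 8).
#' @return A [ConnectivityMatrix-class].
#' @export
bandConnectivity <- function(bands, bandIndex, scrubMask = NULL,
                             subjectId = "s01", session = "pre",
                             minVolumes = 8L) {
  stopifnot(is(bands, "BandSet"))
  bandIndex <- as.integer(bandIndex)
  if (bandIndex < 1L || bandIndex > bands@levels)
    stop(sprintf("bandIndex must be in 1..%d", bands@levels))
  X <- bands@bands[[bandIndex]]
  if (is.null(scrubMask)) scrubMask <- bands@scrubMask
  if (is.null(scrubMask)) scrubMask <- rep(TRUE, ncol(X))
  if (length(scrubMask) != ncol(X))
    stop("scrub mask length does not match volume count")
  keep <- which(scrubMask)
  if (length(keep) == 0L) stop("no retained volumes")
  if (length(keep) < minVolumes)
    stop(sprintf("only %d retained volumes; need at least %d",
                 length(keep), minVolumes))
  Xk <- X[, keep, drop = FALSE]
  sds <- apply(Xk, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning(sprintf("%d region(s) with zero variance over retained volumes; their correlations set to 0: %s",
                    sum(flat),
                    paste(utils::head(bands@regionLabels[flat], 5), collapse = ", ")))
    Xk[flat, ] <- 0
    Xk[flat, 1] <- 1  # placeholder variance; rows zeroed below
  }
  V <- stats::cor(t(Xk))
  if (any(flat)) {
    V[flat, ] <- 0
    V[, flat] <- 0
  }
  V <- (V + t(V)) / 2
  V[V > 1] <- 1
  V[V < -1] <- -1
  diag(V) <- 1
  dimnames(V) <- list(bands@regionLabels, bands@regionLabels)
  new("ConnectivityMatrix", values = V, bandIndex = bandIndex,
      subjectId = subjectId, session = session,
      nVolumesUsed = length(keep))
}

# Column-major upper-triangle index pairs for an n x n matrix: the package's
# canonical ordering of the n(n-1)/2 unique connections.
.edgePairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[, c("row", "col"), drop = FALSE]
}

#' Extract the unique connections of a connectivity matrix
#'
#' @param x a [ConnectivityMatrix-class] or symmetric matrix.
#' @return Numeric vector of the n(n-1)/2 upper-triangle values in the
#'   package's canonical (column-major) edge order.
#' @export
edgeVector <- function(x) {
  v <- if (is(x, "ConnectivityMatrix")) x@values else x
  v[upper.tri(v)]
}
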