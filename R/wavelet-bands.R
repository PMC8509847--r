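# Daubechies-4 (8-tap, 4 vanishing moments) analysis filters, orthonormal
# normalization: |H(w)|^2 + |G(w)|^2 = 2. Values at full double precision.
.db4_lo <- c(-0.01059740178506903, 0.03288301166688520, 0.03084138183556076,
             -0.18703481171909309, -0.02798376941685985, 0.63088076792985890,
             0.71484657055291570, 0.23037781330889650)
.db4_hi <- c(-0.23037781330889650, 0.71484657055291570, -0.63088076792985890,
             -0.02798376941685985, 0.18703481171909309, 0.03084138183556076,
             -0.03288301166688520, -0.01059740178506903)

# DFT of a filter upsampled by factor m, evaluated on the length-T grid.
.filterDft <- function(filt, m, T) {
  om <- 2 * pi * (seq_len(T) - 1) / T
  k <- seq_along(filt) - 1
  exp(-1i * outer(om, m * k)) %*% filt
}

# Zero-phase equivalent transfer functions of the undecimated (a trous)
# wavelet filter bank: one row per detail level 1..levels plus the
# approximation. Row j is the real, non-negative transfer of the
# decompose-then-reconstruct chain for that band under periodic extension,
# so the rows sum to 1 at every frequency (perfect reconstruction) and each
# band output is a circular, shift-equivariant filtering of the input.
.swtBandTransfer <- function(T, levels = 4L) {
  R <- matrix(0, levels + 1L, T)
  prodH <- rep(1, T)
  for (j in seq_len(levels)) {
    m <- 2^(j - 1)
    Gj <- abs(.filterDft(.db4_hi, m, T))^2
    Hj <- abs(.filterDft(.db4_lo, m, T))^2
    R[j, ] <- Gj * prodH / 2^j
    prodH <- prodH * Hj
  }
  R[levels + 1L, ] <- prodH / 2^levels
  R
}

# Filter the rows of X (series along columns) with a set of zero-phase
# transfer functions; returns a list of matrices, one per transfer row.
.applyTransfer <- function(X, R) {
  Z <- stats::mvfft(t(X))                       # T x regions spectra
  lapply(seq_len(nrow(R)), function(j) {
    t(Re(stats::mvfft(Z * R[j, ], inverse = TRUE)) / ncol(X))
  })
}

#' Map wavelet detail levels to frequency bands
#'
#' Dyadic band edges for an undecimated wavelet decomposition of a series
#' sampled every \code{tr} seconds: with Nyquist frequency
#' \eqn{f_N = 1/(2\,tr)}, detail level \eqn{j} spans
#' \eqn{(f_N/2^j,\; f_N/2^{j-1})} Hz. At TR = 2 s the four detail levels
#' cover 0.125-0.25, 0.0625-0.125, 0.03125-0.0625 and 0.015625-0.03125 Hz,
#' the four bands in which resting-state connectivity is analyzed.
#'
#' @param tr repetition time in seconds (> 0).
#' @param levels number of detail levels (>= 1).
#' @return Numeric matrix with one row per level and columns \code{low},
#'   \code{high} (Hz), finest band first.
#' @examples
#' bandFrequencyRanges(2, 4)
#' @export
bandFrequencyRanges <- function(tr, levels = 4L) {
  stopifnot(tr > 0, levels >= 1)
  fN <- 1 / (2 * tr)
  j <- seq_len(levels)
  cbind(low = fN / 2^j, high = fN / 2^(j - 1))
}

#' Undecimated wavelet band decomposition
#'
#' Decomposes each region's time series into \code{levels} detail bands and
#' an approximation using the stationary (undecimated, translation-invariant)
#' discrete wavelet transform with the db4 wavelet: downsamplers are removed
#' and the filters are upsampled at each level. Outputs are per-level detail
#' \emph{reconstructions} (band-limited series the same length as the input),
#' so the details plus the approximation sum exactly back to the input.
#'
#' Boundary handling is periodic (circular) by default, which makes the
#' transform exactly shift-equivariant: circularly shifting the input shifts
#' every band identically. \code{boundary = "symmetric"} instead
#' reflect-pads the series, trading exact shift equivariance for less
#' wrap-around at the series ends.
#'
#' @param x an [RoiTimeseries-class], or a numeric matrix (regions x volumes)
#'   or vector.
#' @param levels number of detail levels (default 4).
#' @param boundary \code{"periodic"} (default) or \code{"symmetric"}.
#' @param tr repetition time in seconds; taken from the object when \code{x}
#'   is an [RoiTimeseries-class].
#' @return A [BandSet-class].
#' @examples
#' x <- matrix(rnorm(2 * 128), 2)
#' bs <- sdwtDecompose(x, tr = 2)
#' recon <- Reduce(`+`, bs@bands) + bs@approximation
#' max(abs(recon - x))  # perfect reconstruction
#' @export
setGeneric("sdwtDecompose",
  function(x, levels = 4L, boundary = c("periodic", "symmetric"), tr = 2)
    standardGeneric("sdwtDecompose"))

.sdwtCore <- function(X, levels, boundary, tr, regionLabels, scrub) {
  T <- ncol(X)
  if (T < 32)
    stop(sprintf("series too short for a stable %d-level undecimated db4 transform: need >= 32 volumes, got %d",
                 levels, T))
  if (boundary == "symmetric") {
    Xe <- cbind(X, X[, rev(seq_len(T)), drop = FALSE])
    R <- .swtBandTransfer(2L * T, levels)
    out <- lapply(.applyTransfer(Xe, R), function(M) M[, seq_len(T), drop = FALSE])
  } else {
    R <- .swtBandTransfer(T, levels)
    out <- .applyTransfer(X, R)
  }
  new("BandSet",
      bands = out[seq_len(levels)],
      approximation = out[[levels + 1L]],
      bandRanges = bandFrequencyRanges(tr, levels),
      waveletName = "db4",
      levels = as.integer(levels),
      tr = tr,
      regionLabels = regionLabels,
      scrubMask = scrub)
}

#' @rdname sdwtDecompose
setMethod("sdwtDecompose", "RoiTimeseries",
  function(x, levels = 4L, boundary = c("periodic", "symmetric"), tr = 2) {
    boundary <- match.arg(boundary)
    .sdwtCore(x@data, as.integer(levels), boundary, x@tr, x@regionLabels,
              x@scrubMask)
  })

#' @rdname sdwtDecompose
setMethod("sdwtDecompose", "matrix",
  function(x, levels = 4L, boundary = c("periodic", "symmetric"), tr = 2) {
    boundary <- match.arg(boundary)
    labs <- rownames(x)
    if (is.null(labs)) labs <- sprintf("R%02d", seq_len(nrow(x)))
    .sdwtCore(x, as.integer(levels), boundary, tr, labs, NULL)
  })

#' @rdname sdwtDecompose
setMethod("sdwtDecompose", "numeric",
  function(x, levels = 4L, boundary = c("periodic", "symmetric"), tr = 2) {
    boundary <- match.arg(boundary)
    .sdwtCore(matrix(x, 1L), as.integer(levels), match.arg(boundary), tr,
              "R01", NULL)
  })
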