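#' @import methods
NULL

setClassUnion("logicalOrNULL", c("logical", "NULL"))
setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Region-of-interest time series for one subject and session
#'
#' Holds the regions-by-volumes signal matrix extracted from a parcellation
#' (by default the 76-region Desikan-Killiany scheme), together with the
#' repetition time and an optional scrub mask marking retained volumes.
#'
#' @slot data numeric matrix, regions x volumes.
#' @slot regionLabels character vector of region names, one per row.
#' @slot tr repetition time in seconds.
#' @slot subjectId subject identifier.
#' @slot session session label, \code{"pre"} or \code{"post"}.
#' @slot scrubMask optional logical vector per volume; \code{TRUE} = retained.
#'
#' @seealso [roiTimeseries()], [sdwtDecompose()], [applyScrub()]
#' @export
setClass("RoiTimeseries",
  representation(
    data = "matrix",
    regionLabels = "character",
    tr = "numeric",
    subjectId = "character",
    session = "character",
    scrubMask = "logicalOrNULL"
  ),
  prototype(tr = 2, subjectId = "s01", session = "pre", scrubMask = NULL)
)

setValidity("RoiTimeseries", function(object) {
  msg <- character()
  d <- object@data
  if (!is.numeric(d)) msg <- c(msg, "data must be a numeric matrix")
  if (anyNA(d)) msg <- c(msg, "data contains missing values")
  if (nrow(d) != length(object@regionLabels))
    msg <- c(msg, sprintf("region count (%d) does not match label count (%d)",
                          nrow(d), length(object@regionLabels)))
  if (ncol(d) < 32)
    msg <- c(msg, sprintf(
      "need at least 32 volumes for a stable 4-level undecimated db4 transform, got %d",
      ncol(d)))
  if (length(object@tr) != 1L || object@tr <= 0) msg <- c(msg, "tr must be a positive scalar")
  if (!object@session %in% c("pre", "post"))
    msg <- c(msg, "session must be 'pre' or 'post'")
  if (!is.null(object@scrubMask) && length(object@scrubMask) != ncol(d))
    msg <- c(msg, "scrubMask length must equal volume count")
  if (length(msg)) msg else TRUE
})

#' Motion trace for scrubbing
#'
#' Per-volume framewise displacement (FD) and DVARS-like derivative
#' root-mean-square values, the two quantities the volume-scrubbing rule
#' thresholds (FD > 0.5, DVARS > 8).
#'
#' @slot fd non-negative numeric vector, one value per volume.
#' @slot dvars non-negative numeric vector, one value per volume.
#'
#' @seealso [computeScrubMask()], [generateMotionTrace()]
#' @export
setClass("MotionTrace",
  representation(fd = "numeric", dvars = "numeric"))

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (length(object@fd) != length(object@dvars))
    msg <- c(msg, "fd and dvars must have equal length")
  if (length(object@fd) == 0L) msg <- c(msg, "trace is empty")
  if (any(object@fd < 0) || any(object@dvars < 0))
    msg <- c(msg, "fd and dvars must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Wavelet band decomposition of an ROI time series
#'
#' Per-level detail reconstructions from an undecimated (stationary) discrete
#' wavelet transform. Each band matrix has the same regions-by-volumes shape
#' as the input, and the four details plus the approximation sum back to the
#' input (perfect reconstruction).
#'
#' @slot bands list of detail matrices, finest (level 1) first.
#' @slot approximation the level-L approximation matrix.
#' @slot bandRanges numeric matrix with columns \code{low}, \code{high} (Hz).
#' @slot waveletName wavelet identifier (\code{"db4"}).
#' @slot levels number of decomposition levels.
#' @slot tr repetition time in seconds.
#' @slot regionLabels region names.
#' @slot scrubMask carried over from the source series (or NULL).
#'
#' @seealso [sdwtDecompose()], [bandConnectivity()]
#' @export
setClass("BandSet",
  representation(
    bands = "list",
    approximation = "matrix",
    bandRanges = "matrix",
    waveletName = "character",
    levels = "integer",
    tr = "numeric",
    regionLabels = "character",
    scrubMask = "logicalOrNULL"
  ))

setValidity("BandSet", function(object) {
  msg <- character()
  if (length(object@bands) != object@levels)
    msg <- c(msg, "number of band matrices must equal levels")
  dims <- vapply(object@bands, dim, integer(2))
  if (length(object@bands) && !all(dims == dim(object@approximation)))
    msg <- c(msg, "all band matrices must share the approximation's shape")
  if (nrow(object@bandRanges) != object@levels)
    msg <- c(msg, "bandRanges must have one row per level")
  if (length(msg)) msg else TRUE
})

#' Per-band functional connectivity matrix
#'
#' Symmetric, unit-diagonal Pearson correlation matrix between region band
#' series for one subject, session and frequency band. For 76 regions the
#' upper triangle holds the 2850 unique connections.
#'
#' @slot values symmetric numeric matrix with unit diagonal.
#' @slot bandIndex wavelet detail level (1 = finest).
#' @slot subjectId,session provenance of the source series.
#' @slot nVolumesUsed number of volumes retained after scrubbing.
#'
#' @seealso [bandConnectivity()], [thresholdByDensity()]
#' @export
setClass("ConnectivityMatrix",
  representation(
    values = "matrix",
    bandIndex = "integer",
    subjectId = "character",
    session = "character",
    nVolumesUsed = "integer"
  ))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  else {
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "values must be symmetric to 1e-12")
    if (max(abs(diag(v) - 1)) > 0) msg <- c(msg, "diagonal must be exactly 1")
    off <- v[upper.tri(v)]
    if (length(off) && (min(off) < -1 || max(off) > 1))
      msg <- c(msg, "off-diagonal entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Binary graphs across a density grid
#'
#' Result of proportional thresholding of one weighted connectivity matrix at
#' each density of a grid: the strongest positive connections are kept as
#' binary edges, so edge sets are nested along the grid.
#'
#' @slot source the [ConnectivityMatrix-class] that was thresholded.
#' @slot densities numeric density grid (fractions of possible edges).
#' @slot graphs list of \pkg{igraph} graphs, one per density.
#'
#' @seealso [densityGraphStack()], [metricCurves()]
#' @export
setClass("DensityGraphStack",
  representation(
    source = "ConnectivityMatrix",
    densities = "numeric",
    graphs = "list"
  ))

setValidity("DensityGraphStack", function(object) {
  msg <- character()
  if (length(object@densities) != length(object@graphs))
    msg <- c(msg, "one graph per density required")
  if (any(object@densities <= 0) || any(object@densities > 1))
    msg <- c(msg, "densities must lie in (0, 1]")
  if (is.unsorted(object@densities, strictly = TRUE))
    msg <- c(msg, "densities must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Result of a paired sign-permutation test
#'
#' @slot observedD observed mean paired difference.
#' @slot p empirical tail probability (one-sided, in the direction of
#'   \code{sign(observedD)}); never 0 because the observed assignment counts.
#' @slot nRealizations number of sign assignments evaluated.
#' @slot exhaustive whether all 2^n assignments were enumerated.
#' @slot effectSizeD Cohen's d with pooled standard deviation.
#' @slot power two-sided one-sample t-test power at alpha = 0.05.
#'
#' @seealso [signPermutationTest()]
#' @export
setClass("PermutationResult",
  representation(
    observedD = "numeric",
    p = "numeric",
    nRealizations = "numeric",
    exhaustive = "logical",
    effectSizeD = "numeric",
    power = "numeric"
  ))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@p > 1 || object@p < 0) msg <- c(msg, "p must lie in [0, 1]")
  if (object@p < 1 / object@nRealizations - 1e-15)
    msg <- c(msg, "p cannot beat the permutation resolution 1/nRealizations")
  if (length(msg)) msg else TRUE
})

#' FDR-selected subnetwork of significantly changed connections
#'
#' Edge set surviving Benjamini-Hochberg selection at the stated level within
#' one frequency band, with the within-subnetwork nodal degree (number of
#' selected connections incident to each region).
#'
#' @slot band frequency band index.
#' @slot alpha FDR level used for selection.
#' @slot edges data.frame with columns \code{i}, \code{j}, \code{p},
#'   \code{direction} (+1 increase, -1 decrease).
#' @slot withinSubnetworkDegree named integer vector over all regions.
#'
#' @seealso [buildFdrSubnetwork()]
#' @export
setClass("Subnetwork",
  representation(
    band = "integer",
    alpha = "numeric",
    edges = "data.frame",
    withinSubnetworkDegree = "integer"
  ))

setValidity("Subnetwork", function(object) {
  msg <- character()
  need <- c("i", "j", "p", "direction")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, "edges needs columns i, j, p, direction")
  else if (nrow(object@edges)) {
    tab <- table(factor(c(object@edges$i, object@edges$j),
                        levels = seq_along(object@withinSubnetworkDegree)))
    if (!all(as.integer(tab) == object@withinSubnetworkDegree))
      msg <- c(msg, "withinSubnetworkDegree must count incident selected edges")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic paired cohort
#'
#' Defines the study conditions a simulated pre/post cohort emulates: cohort
#' size, scan length, repetition time, per-band target connectivity (a modular
#' template or explicit matrices), planted post-treatment connectivity changes
#' and broadband noise level.
#'
#' @slot nSubjects,nRegions,nVolumes cohort dimensions.
#' @slot tr repetition time (seconds).
#' @slot baseConnectivity list of per-band target correlation matrices
#'   (length = number of analysis bands).
#' @slot effectEdges data.frame with columns \code{i}, \code{j}, \code{band},
#'   \code{delta} applied to post-session targets.
#' @slot noiseSd broadband measurement-noise standard deviation, relative to
#'   unit-variance band sources.
#' @slot clinicalSim optional list describing simulated clinical scores
#'   (see [generateCohort()]).
#' @slot seed integer random seed.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    nRegions = "integer",
    nVolumes = "integer",
    tr = "numeric",
    baseConnectivity = "list",
    effectEdges = "data.frame",
    noiseSd = "numeric",
    clinicalSim = "list",
    seed = "integer"
  ))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 2) msg <- c(msg, "need at least 2 subjects")
  if (object@nVolumes < 32) msg <- c(msg, "need at least 32 volumes")
  for (b in seq_along(object@baseConnectivity)) {
    S <- object@baseConnectivity[[b]]
    if (!isSymmetric(S, tol = 1e-10))
      msg <- c(msg, sprintf("band %d target matrix is not symmetric", b))
    if (max(abs(diag(S) - 1)) > 1e-12)
      msg <- c(msg, sprintf("band %d target matrix must have unit diagonal", b))
  }
  ee <- object@effectEdges
  if (nrow(ee)) {
    if (!all(c("i", "j", "band", "delta") %in% names(ee)))
      msg <- c(msg, "effectEdges needs columns i, j, band, delta")
    else if (any(ee$i == ee$j)) msg <- c(msg, "effectEdges cannot be self-pairs")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A generated paired pre/post cohort
#'
#' @slot pre,post lists of [RoiTimeseries-class], same subject order.
#' @slot groundTruth list with per-band target (analysis-scale) correlation
#'   matrices for \code{pre} and \code{post}.
#' @slot clinical optional per-subject data.frame (scores, age, sex, iq).
#' @slot spec the generating [CohortSpec-class].
#'
#' @seealso [generateCohort()]
#' @export
setClass("PairedCohort",
  representation(
    pre = "list",
    post = "list",
    groundTruth = "list",
    clinical = "data.frameOrNULL",
    spec = "CohortSpec"
  ))

setValidity("PairedCohort", function(object) {
  msg <- character()
  if (length(object@pre) != length(object@post))
    msg <- c(msg, "pre and post must have equal length")
  idPre <- vapply(object@pre, function(x) x@subjectId, character(1))
  idPost <- vapply(object@post, function(x) x@subjectId, character(1))
  if (!identical(idPre, idPost))
    msg <- c(msg, "subject ordering must be identical in pre and post")
  if (length(msg)) msg else TRUE
})

#' A metric traced over the density grid with its AUC summary
#'
#' @slot metric metric name.
#' @slot densities density grid.
#' @slot values metric value per density (vector for global metrics, matrix
#'   nodes x densities for nodal metrics).
#' @slot auc mean over the uniform grid (vector or per-node).
#'
#' @seealso [metricCurves()]
#' @export
setClass("MetricCurve",
  representation(
    metric = "character",
    densities = "numeric",
    values = "ANY",
    auc = "numeric"
  ))
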