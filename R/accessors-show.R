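#' @rdname accessors
#' @aliases roiData,RoiTimeseries-method
setMethod("roiData", "RoiTimeseries", function(x) x@data)
#' @rdname accessors
setMethod("regionLabels", "RoiTimeseries", function(x) x@regionLabels)
#' @rdname accessors
setMethod("regionLabels", "BandSet", function(x) x@regionLabels)
#' @rdname accessors
setMethod("repetitionTime", "RoiTimeseries", function(x) x@tr)
#' @rdname accessors
setMethod("repetitionTime", "BandSet", function(x) x@tr)
#' @rdname accessors
setMethod("subjectId", "RoiTimeseries", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "ConnectivityMatrix", function(x) x@subjectId)
#' @rdname accessors
setMethod("sessionLabel", "RoiTimeseries", function(x) x@session)
#' @rdname accessors
setMethod("sessionLabel", "ConnectivityMatrix", function(x) x@session)
#' @rdname accessors
setMethod("scrubMask", "RoiTimeseries", function(x) x@scrubMask)
#' @rdname accessors
setMethod("scrubMask", "BandSet", function(x) x@scrubMask)
#' @rdname accessors
setMethod("bandValues", "ConnectivityMatrix", function(x) x@values)
#' @rdname accessors
setMethod("bandIndex", "ConnectivityMatrix", function(x) x@bandIndex)
#' @rdname accessors
setMethod("bandRanges", "BandSet", function(x) x@bandRanges)
#' @rdname accessors
setMethod("densities", "DensityGraphStack", function(x) x@densities)
#' @rdname accessors
setMethod("densities", "MetricCurve", function(x) x@densities)
#' @rdname accessors
setMethod("stackGraphs", "DensityGraphStack", function(x) x@graphs)
#' @rdname accessors
setMethod("subnetworkEdges", "Subnetwork", function(x) x@edges)
#' @rdname accessors
setMethod("subnetworkDegree", "Subnetwork", function(x) x@withinSubnetworkDegree)
#' @rdname accessors
setMethod("aucOf", "MetricCurve", function(x) x@auc)

setMethod("show", "RoiTimeseries", function(object) {
  cat(sprintf("RoiTimeseries: %d regions x %d volumes (TR = %gs)\n",
              nrow(object@data), ncol(object@data), object@tr))
  cat(sprintf("  subject %s, session %s", object@subjectId, object@session))
  if (!is.null(object@scrubMask))
    cat(sprintf(", %d/%d volumes retained", sum(object@scrubMask),
                length(object@scrubMask)))
  cat("\n")
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace: %d volumes, %d above FD 0.5, %d above DVARS 8\n",
              length(object@fd), sum(object@fd > 0.5), sum(object@dvars > 8)))
})

setMethod("show", "BandSet", function(object) {
  cat(sprintf("BandSet: %d-level %s undecimated decomposition, %d regions x %d volumes\n",
              object@levels, object@waveletName,
              nrow(object@approximation), ncol(object@approximation)))
  for (j in seq_len(object@levels))
    cat(sprintf("  band %d: %.4g-%.4g Hz\n", j,
                object@bandRanges[j, 1], object@bandRanges[j, 2]))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@values)
  cat(sprintf("ConnectivityMatrix: %d x %d (%d connections), band %d\n",
              n, n, n * (n - 1) / 2, object@bandIndex))
  cat(sprintf("  subject %s, session %s, %d volumes used\n",
              object@subjectId, object@session, object@nVolumesUsed))
})

setMethod("show", "DensityGraphStack", function(object) {
  cat(sprintf("DensityGraphStack: %d densities in [%.2f, %.2f]\n",
              length(object@densities), min(object@densities),
              max(object@densities)))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("Sign-permutation test (%s, %g realizations)\n",
              if (object@exhaustive) "exhaustive" else "sampled",
              object@nRealizations))
  cat(sprintf("  D = %.4g, p = %.6g, Cohen's d = %.4g, power = %.4g\n",
              object@observedD, object@p, object@effectSizeD, object@power))
})

setMethod("show", "Subnetwork", function(object) {
  cat(sprintf("Subnetwork (band %d, FDR alpha = %g): %d connections, %d regions involved\n",
              object@band, object@alpha, nrow(object@edges),
              sum(object@withinSubnetworkDegree > 0)))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d subjects, %d regions x %d volumes, TR = %gs, %d planted effects, seed %d\n",
              object@nSubjects, object@nRegions, object@nVolumes, object@tr,
              nrow(object@effectEdges), object@seed))
})

setMethod("show", "PairedCohort", function(object) {
  cat(sprintf("PairedCohort: %d paired subjects, %d regions x %d volumes\n",
              length(object@pre), object@spec@nRegions, object@spec@nVolumes))
})

setMethod("show", "MetricCurve", function(object) {
  cat(sprintf("MetricCurve '%s' over %d densities; AUC %s\n",
              object@metric, length(object@densities),
              if (length(object@auc) == 1L) sprintf("= %.4g", object@auc)
              else sprintf("per node (mean %.4g)", mean(object@auc))))
})
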