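#' @name accessors
#' @title Accessors for fbandnet classes
#'
#' @description Small accessor generics for the package's S4 containers:
#' \code{roiData} (signal matrix), \code{regionLabels}, \code{repetitionTime},
#' \code{subjectId}, \code{sessionLabel}, \code{scrubMask}, \code{bandValues}
#' (connectivity matrix), \code{bandIndex}, \code{bandRanges},
#' \code{densities}, \code{stackGraphs}, \code{subnetworkEdges},
#' \code{subnetworkDegree}, \code{aucOf}.
#'
#' @param x an fbandnet object.
#' @return The slot content named by the accessor.
NULL

#' @rdname accessors
#' @export
setGeneric("roiData", function(x) standardGeneric("roiData"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("sessionLabel", function(x) standardGeneric("sessionLabel"))
#' @rdname accessors
#' @export
setGeneric("scrubMask", function(x) standardGeneric("scrubMask"))
#' @rdname accessors
#' @export
setGeneric("bandValues", function(x) standardGeneric("bandValues"))
#' @rdname accessors
#' @export
setGeneric("bandIndex", function(x) standardGeneric("bandIndex"))
#' @rdname accessors
#' @export
setGeneric("bandRanges", function(x) standardGeneric("bandRanges"))
#' @rdname accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))
#' @rdname accessors
#' @export
setGeneric("stackGraphs", function(x) standardGeneric("stackGraphs"))
#' @rdname accessors
#' @export
setGeneric("subnetworkEdges", function(x) standardGeneric("subnetworkEdges"))
#' @rdname accessors
#' @export
setGeneric("subnetworkDegree", function(x) standardGeneric("subnetworkDegree"))
#' @rdname accessors
#' @export
setGeneric("aucOf", function(x) standardGeneric("aucOf"))
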