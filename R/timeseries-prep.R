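#' Construct an RoiTimeseries
#'
#' @param data numeric matrix, regions x volumes.
#' @param regionLabels region names; defaults to rownames or \code{R01..}.
#' @param tr repetition time in seconds.
#' @param subjectId subject identifier.
#' @param session \code{"pre"} or \code{"post"}.
#' @param scrubMask optional logical retained-volume mask.
#' @return An [RoiTimeseries-class].
#' @export
roiTimeseries <- function(data, regionLabels = NULL, tr = 2,
                          subjectId = "s01", session = "pre",
                          scrubMask = NULL) {
  data <- as.matrix(data)
  if (is.null(regionLabels)) {
    regionLabels <- rownames(data)
    if (is.null(regionLabels)) regionLabels <- sprintf("R%02d", seq_len(nrow(data)))
  }
  rownames(data) <- regionLabels
  new("RoiTimeseries", data = data, regionLabels = regionLabels, tr = tr,
      subjectId = subjectId, session = session, scrubMask = scrubMask)
}

#' Construct a MotionTrace
#'
#' @param fd framewise displacement per volume.
#' @param dvars DVARS-like derivative root-mean-square value per volume.
#' @return A [MotionTrace-class].
#' @export
motionTrace <- function(fd, dvars) new("MotionTrace", fd = fd, dvars = dvars)

#' Volume scrubbing mask from a motion trace
#'
#' A volume is an offender when its framewise displacement exceeds
#' \code{fdThreshold} and/or its DVARS value exceeds \code{dvarsThreshold}.
#' Every offender is excluded together with the volume immediately before it
#' and the two volumes after it; overlapping exclusion windows are unioned
#' and windows truncate at the series boundaries.
#'
#' @param trace a [MotionTrace-class].
#' @param fdThreshold framewise-displacement threshold (default 0.5).
#' @param dvarsThreshold DVARS threshold (default 8).
#' @return Logical vector, \code{TRUE} for retained volumes.
#' @examples
#' tr <- motionTrace(fd = c(rep(0.1, 10), 0.9, rep(0.1, 9)), dvars = rep(1, 20))
#' which(!computeScrubMask(tr))  # 10:13 (offender 11, one before, two after)
#' @export
computeScrubMask <- function(trace, fdThreshold = 0.5, dvarsThreshold = 8) {
  stopifnot(is(trace, "MotionTrace"), fdThreshold > 0, dvarsThreshold > 0)
  T <- length(trace@fd)
  if (T == 0L) stop("empty motion trace")
  offender <- trace@fd > fdThreshold | trace@dvars > dvarsThreshold
  excluded <- rep(FALSE, T)
  for (t in which(offender)) {
    w <- max(1L, t - 1L):min(T, t + 2L)
    excluded[w] <- TRUE
  }
  !excluded
}

#' Regress nuisance signals out of every region's series
#'
#' Replaces each region's series by its least-squares residual against an
#' intercept plus the given nuisance columns (e.g., mean CSF and white-matter
#' signals). Residuals are exactly orthogonal to every nuisance column; the
#' operation is a projection, hence idempotent.
#'
#' @param ts an [RoiTimeseries-class].
#' @param nuisance numeric matrix, volumes x k.
#' @return The [RoiTimeseries-class] with residual series.
#' @export
regressNuisance <- function(ts, nuisance) {
  stopifnot(is(ts, "RoiTimeseries"))
  nuisance <- as.matrix(nuisance)
  T <- ncol(ts@data)
  if (nrow(nuisance) != T)
    stop(sprintf("nuisance has %d rows but the series has %d volumes",
                 nrow(nuisance), T))
  X <- cbind(1, nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop(sprintf("rank-deficient nuisance design; dependent column(s): %s",
                 paste(dep - 1L, collapse = ", ")))
  }
  resid <- t(qr.resid(qrX, t(ts@data)))
  dimnames(resid) <- dimnames(ts@data)
  initialize(ts, data = resid)
}

#' Attach a scrub mask to a time series
#'
#' Flags censored volumes without deleting them: the contiguous series is
#' kept intact for wavelet filtering and censored volumes are dropped
#' pairwise later, at the correlation step.
#'
#' @param ts an [RoiTimeseries-class].
#' @param mask logical retained-volume vector, one entry per volume.
#' @return The [RoiTimeseries-class] with \code{scrubMask} set.
#' @export
applyScrub <- function(ts, mask) {
  stopifnot(is(ts, "RoiTimeseries"))
  if (length(mask) != ncol(ts@data))
    stop(sprintf("mask length %d does not match %d volumes",
                 length(mask), ncol(ts@data)))
  initialize(ts, scrubMask = as.logical(mask))
}

#' Read / write ROI time series as TSV
#'
#' Tab-separated text with a header row: first column \code{region}, then one
#' column per volume (\code{V1..VT}); rows are regions.
#'
#' @param path file path.
#' @param tr,subjectId,session metadata for the constructed object.
#' @return [readRoiTimeseries()] returns an [RoiTimeseries-class];
#'   [writeRoiTimeseries()] returns \code{path} invisibly.
#' @export
readRoiTimeseries <- function(path, tr = 2, subjectId = "s01",
                              session = "pre") {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"region" %in% names(df))
    stop(sprintf("%s: missing 'region' column", path))
  m <- as.matrix(df[, setdiff(names(df), "region"), drop = FALSE])
  dimnames(m) <- NULL
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(apply(m, 1, function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop(sprintf("%s: malformed value(s) at data row(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  roiTimeseries(m, regionLabels = as.character(df$region), tr = tr,
                subjectId = subjectId, session = session)
}

#' @rdname readRoiTimeseries
#' @param ts an [RoiTimeseries-class] to write.
#' @export
writeRoiTimeseries <- function(ts, path) {
  df <- data.frame(region = ts@regionLabels, ts@data, check.names = FALSE)
  colnames(df) <- c("region", sprintf("V%d", seq_len(ncol(ts@data))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
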