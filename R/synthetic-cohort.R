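#' Modular connectivity template
#'
#' Block-structured correlation matrix: regions are split into
#' \code{nModules} contiguous modules with correlation \code{withinR} inside
#' a module and \code{betweenR} between modules.
#'
#' @param nRegions number of regions.
#' @param nModules number of equal (as near as possible) modules.
#' @param withinR,betweenR correlations inside / between modules.
#' @return Symmetric unit-diagonal correlation matrix.
#' @export
modularTemplate <- function(nRegions = 76L, nModules = 4L,
                            withinR = 0.5, betweenR = 0.1) {
  mod <- rep(seq_len(nModules), length.out = nRegions)
  mod <- sort(mod)
  S <- matrix(betweenR, nRegions, nRegions)
  for (m in seq_len(nModules)) {
    idx <- mod == m
    S[idx, idx] <- withinR
  }
  diag(S) <- 1
  S
}

#' Specify a synthetic paired cohort
#'
#' Builds a [CohortSpec-class] describing a paired pre/post resting-state
#' cohort: by default 12 subjects, 76 regions, 180 volumes at TR = 2 s with
#' a 4-module connectivity template shared by the four analysis bands.
#' Post-treatment sessions differ from baseline only at \code{effectEdges},
#' where the stated delta is added to the target correlation of that edge in
#' that band.
#'
#' @param nSubjects,nRegions,nVolumes,tr cohort dimensions and sampling.
#' @param baseConnectivity per-band target (analysis-scale) correlation: a
#'   single matrix recycled over the four bands, a list of four matrices, or
#'   \code{NULL} for the default [modularTemplate()].
#' @param effectEdges data.frame with columns \code{i}, \code{j},
#'   \code{band}, \code{delta}; empty by default.
#' @param noiseSd broadband measurement-noise SD relative to unit-variance
#'   band sources (default 0.3).
#' @param clinicalSim optional list with elements \code{edge} (length-2
#'   region pair), \code{band}, \code{slope}, \code{intercept},
#'   \code{noiseSd}: simulated clinical change is
#'   \code{intercept + slope * (realized connectivity change on that edge)
#'   + noise}.
#' @param seed integer seed.
#' @param nBands number of analysis bands (default 4).
#' @return A validated [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjects = 12L, nRegions = 76L, nVolumes = 180L,
                       tr = 2, baseConnectivity = NULL,
                       effectEdges = NULL, noiseSd = 0.3,
                       clinicalSim = list(), seed = 1L, nBands = 4L) {
  if (is.null(baseConnectivity))
    baseConnectivity <- modularTemplate(nRegions)
  if (is.matrix(baseConnectivity))
    baseConnectivity <- rep(list(baseConnectivity), nBands)
  stopifnot(length(baseConnectivity) == nBands)
  if (is.null(effectEdges))
    effectEdges <- data.frame(i = integer(0), j = integer(0),
                              band = integer(0), delta = numeric(0))
  new("CohortSpec",
      nSubjects = as.integer(nSubjects), nRegions = as.integer(nRegions),
      nVolumes = as.integer(nVolumes), tr = tr,
      baseConnectivity = baseConnectivity,
      effectEdges = effectEdges, noiseSd = noiseSd,
      clinicalSim = clinicalSim, seed = as.integer(seed))
}

# Apply planted deltas to per-band target matrices; reject invalid values.
.applyEffects <- function(targets, effectEdges) {
  if (!nrow(effectEdges)) return(targets)
  for (r in seq_len(nrow(effectEdges))) {
    b <- effectEdges$band[r]
    i <- effectEdges$i[r]; j <- effectEdges$j[r]
    v <- targets[[b]][i, j] + effectEdges$delta[r]
    if (abs(v) > 1)
      stop(sprintf("effect on edge (%d, %d) in band %d drives the target correlation to %.3f, outside [-1, 1]",
                   i, j, b, v))
    targets[[b]][i, j] <- v
    targets[[b]][j, i] <- v
  }
  targets
}

# Inter-band mixing of the generator: sources synthesized with band filter
# R_b' and re-analyzed with band filter R_b mix with weights
# v[b, b'] = mean(R_b^2 R_b'^2) / mean(R_b'^2); broadband noise of unit
# variance contributes mean(R_b^2) to the analyzed band-b variance.
.bandMixing <- function(T, nBands) {
  R <- .swtBandTransfer(T, nBands)[seq_len(nBands), , drop = FALSE]
  R2 <- R^2
  e <- rowMeans(R2)                    # per-band filter energy
  V <- (R2 %*% t(R2)) / (T * rep(e, each = nBands))
  dim(V) <- c(nBands, nBands)
  list(V = V, noiseWeight = e, transfer = R)
}

# Solve the mixing so that ANALYZED band correlations equal the requested
# targets: per edge, V s = diag(total variance) t. Returns per-band source
# correlation matrices (unit diagonal), PSD-projected or rejected.
.compensateTargets <- function(targets, mix, noiseSd, label,
                               rejectNonPsd = FALSE, effectEdges = NULL) {
  nBands <- length(targets)
  n <- nrow(targets[[1]])
  denom <- rowSums(mix$V) + noiseSd^2 * mix$noiseWeight
  Tm <- vapply(targets, function(S) S[upper.tri(S)],
               numeric(n * (n - 1) / 2))
  Sm <- solve(mix$V, t(Tm) * denom)    # nBands x npairs
  if (max(abs(Sm)) > 1) {
    k <- which.max(apply(abs(Sm), 2, max))
    pr <- .edgePairs(n)[k, ]
    stop(sprintf("%s: requested correlations are infeasible after leakage/noise compensation (edge (%d, %d) needs source correlation %.3f); lower noiseSd or the planted values",
                 label, pr[1], pr[2], max(abs(Sm))))
  }
  out <- vector("list", nBands)
  for (b in seq_len(nBands)) {
    S <- matrix(0, n, n)
    S[upper.tri(S)] <- Sm[b, ]
    S <- S + t(S)
    diag(S) <- 1
    if (!.isPsd(S)) {
      if (rejectNonPsd) {
        ee <- effectEdges[effectEdges$band == b, , drop = FALSE]
        stop(sprintf("%s: band %d target is not positive semidefinite after applying effect edge(s) %s",
                     label, b,
                     paste(sprintf("(%d, %d)", ee$i, ee$j), collapse = ", ")))
      }
      warning(sprintf("%s: band %d compensated target projected to the nearest correlation matrix",
                      label, b))
      S <- .nearestCorrelation(S)
    }
    out[[b]] <- S
  }
  out
}

# Square-root factor of a (projected) correlation matrix.
.corFactor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# One session: sum over bands of band-filtered, cross-correlated Gaussian
# sources, plus broadband noise.
.simulateSession <- function(factors, mix, noiseSd, n, T) {
  X <- matrix(0, n, T)
  for (b in seq_along(factors)) {
    E <- matrix(stats::rnorm(n * T), n, T)
    Fb <- .applyTransfer(E, mix$transfer[b, , drop = FALSE])[[1]]
    Fb <- Fb / sqrt(mix$noiseWeight[b])   # unit variance per band source
    X <- X + factors[[b]] %*% Fb
  }
  if (noiseSd > 0) X <- X + noiseSd * matrix(stats::rnorm(n * T), n, T)
  X
}

#' Generate a paired pre/post cohort with known band structure
#'
#' Synthesizes, for each subject and session, a sum over frequency bands of
#' band-limited Gaussian processes. Each band source is white noise shaped
#' by the same wavelet band-reconstruction filter the analysis applies, and
#' cross-regional structure is imposed by a matrix square root of a per-band
#' source correlation matrix. Because the analysis filters leak across
#' neighboring dyadic bands and broadband noise dilutes every band, the
#' generator first solves this (exactly known) linear mixing so that the
#' \emph{analyzed} per-band correlations converge to the requested ground
#' truth as the series grows. Post sessions differ from baseline only at the
#' spec's \code{effectEdges}.
#'
#' Requested values that become non-positive-semidefinite after applying a
#' planted effect are rejected with a diagnostic naming the offending
#' edge(s); a non-PSD \emph{baseline} template is projected to the nearest
#' correlation matrix with a warning.
#'
#' With \code{clinicalSim} set, per-subject clinical change scores are drawn
#' as a stated linear function of the subject's realized connectivity change
#' on a chosen edge/band plus Gaussian noise, alongside age, sex and IQ
#' covariates.
#'
#' Re-running with the same spec reproduces the cohort exactly.
#'
#' @param spec a [CohortSpec-class].
#' @param boundary wavelet boundary handling for the internal analysis used
#'   by \code{clinicalSim} features.
#' @return A [PairedCohort-class].
#' @export
generateCohort <- function(spec, boundary = "periodic") {
  stopifnot(is(spec, "CohortSpec"))
  n <- spec@nRegions
  T <- spec@nVolumes
  nBands <- length(spec@baseConnectivity)
  mix <- .bandMixing(T, nBands)
  targetsPre <- lapply(spec@baseConnectivity, function(S) {
    if (!.isPsd(S)) {
      warning("baseline template projected to the nearest correlation matrix")
      S <- .nearestCorrelation(S)
    }
    S
  })
  targetsPost <- .applyEffects(targetsPre, spec@effectEdges)
  srcPre <- .compensateTargets(targetsPre, mix, spec@noiseSd, "pre")
  srcPost <- .compensateTargets(targetsPost, mix, spec@noiseSd, "post",
                                rejectNonPsd = nrow(spec@effectEdges) > 0,
                                effectEdges = spec@effectEdges)
  facPre <- lapply(srcPre, .corFactor)
  facPost <- lapply(srcPost, .corFactor)
  labels <- if (n == 76L) dkRegionLabels() else sprintf("R%02d", seq_len(n))
  set.seed(spec@seed)
  pre <- vector("list", spec@nSubjects)
  post <- vector("list", spec@nSubjects)
  for (s in seq_len(spec@nSubjects)) {
    sid <- sprintf("s%02d", s)
    pre[[s]] <- roiTimeseries(.simulateSession(facPre, mix, spec@noiseSd, n, T),
                              regionLabels = labels, tr = spec@tr,
                              subjectId = sid, session = "pre")
    post[[s]] <- roiTimeseries(.simulateSession(facPost, mix, spec@noiseSd, n, T),
                               regionLabels = labels, tr = spec@tr,
                               subjectId = sid, session = "post")
  }
  clinical <- NULL
  cs <- spec@clinicalSim
  if (length(cs)) {
    stopifnot(all(c("edge", "band", "slope") %in% names(cs)))
    icpt <- if (is.null(cs$intercept)) 0 else cs$intercept
    nsd <- if (is.null(cs$noiseSd)) 1 else cs$noiseSd
    feat <- vapply(seq_len(spec@nSubjects), function(s) {
      rPre <- bandConnectivity(sdwtDecompose(pre[[s]], levels = nBands,
                                             boundary = boundary),
                               cs$band)@values[cs$edge[1], cs$edge[2]]
      rPost <- bandConnectivity(sdwtDecompose(post[[s]], levels = nBands,
                                              boundary = boundary),
                                cs$band)@values[cs$edge[1], cs$edge[2]]
      rPost - rPre
    }, numeric(1))
    change <- icpt + cs$slope * feat + stats::rnorm(spec@nSubjects, 0, nsd)
    preScore <- stats::rnorm(spec@nSubjects, 30, 8)
    clinical <- data.frame(
      subjectId = sprintf("s%02d", seq_len(spec@nSubjects)),
      preScore = preScore, postScore = preScore + change, change = change,
      featureChange = feat,
      age = stats::runif(spec@nSubjects, 12, 19),
      sex = stats::rbinom(spec@nSubjects, 1, 0.5),
      iq = stats::rnorm(spec@nSubjects, 105, 15))
  }
  new("PairedCohort", pre = pre, post = post,
      groundTruth = list(pre = targetsPre, post = targetsPost),
      clinical = clinical, spec = spec)
}

#' Synthetic motion trace with controlled offenders
#'
#' Baseline framewise displacement stays below 0.5 and DVARS below 8; at
#' each index in \code{spikeIndices} (1-based) both quantities exceed their
#' scrubbing thresholds, so the scrubbing rule flags exactly those volumes
#' as offenders.
#'
#' @param nVolumes trace length.
#' @param spikeIndices 1-based offender positions within
#'   \code{1..nVolumes}.
#' @param seed integer seed for the sub-threshold baseline.
#' @return A [MotionTrace-class].
#' @export
generateMotionTrace <- function(nVolumes, spikeIndices = integer(0),
                                seed = 1L) {
  stopifnot(all(spikeIndices >= 1), all(spikeIndices <= nVolumes))
  set.seed(seed)
  fd <- stats::runif(nVolumes, 0.02, 0.35)
  dvars <- stats::runif(nVolumes, 0.5, 6)
  fd[spikeIndices] <- stats::runif(length(spikeIndices), 0.7, 1.5)
  dvars[spikeIndices] <- stats::runif(length(spikeIndices), 9, 15)
  motionTrace(fd, dvars)
}

#' Write a cohort to disk
#'
#' One TSV per subject and session (rows = labeled regions, columns =
#' volumes) plus a JSON manifest recording subjects, sessions, TR, the seed
#' and the planted effects.
#'
#' @param cohort a [PairedCohort-class].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PairedCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (s in seq_along(cohort@pre)) {
    for (sess in c("pre", "post")) {
      ts <- if (sess == "pre") cohort@pre[[s]] else cohort@post[[s]]
      fn <- sprintf("%s_%s.tsv", ts@subjectId, sess)
      writeRoiTimeseries(ts, file.path(dir, fn))
      entries[[length(entries) + 1L]] <-
        list(subject = ts@subjectId, session = sess, file = fn)
    }
  }
  manifest <- list(
    schema = "fbandnet-manifest-1",
    tr = cohort@spec@tr,
    seed = cohort@spec@seed,
    n_subjects = cohort@spec@nSubjects,
    n_regions = cohort@spec@nRegions,
    n_volumes = cohort@spec@nVolumes,
    planted_effects = cohort@spec@effectEdges,
    sessions = entries)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(cohort@clinical))
    utils::write.table(cohort@clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}
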