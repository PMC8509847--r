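# Polynomial rolling hash of a serialized R object, as provenance
# fingerprint (kept in 31 bits to stay in exact-double territory).
.configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build and validate a pipeline run configuration
#'
#' @param manifest path to a cohort manifest JSON (see [writeCohort()]);
#'   ignored when \code{cohort} is given.
#' @param cohort an in-memory [PairedCohort-class] (takes precedence).
#' @param outDir output directory for report tables.
#' @param densities uniform density grid (default 0.10 to 0.50 step 0.01).
#' @param nRand random reference networks per graph (default 100).
#' @param nRealizations sign-permutation realization budget (default 1e6;
#'   cohorts of up to 20 subjects are enumerated exactly).
#' @param seed mandatory integer seed.
#' @param alpha significance / FDR level (default 0.05).
#' @param bands band indices to analyze (default 1:4).
#' @param boundary wavelet boundary handling.
#' @param scrub apply scrub masks carried by the series (default TRUE).
#' @param clinical run exploratory clinical regressions when clinical scores
#'   are available (default TRUE).
#' @param globalCurves compute normalized global metric curves (needs
#'   \code{nRand} references per graph; default TRUE).
#' @return Validated config list of class \code{fbandnetConfig}.
#' @export
runConfig <- function(manifest = NULL, cohort = NULL, outDir = tempfile("fbandnet_"),
                      densities = seq(0.10, 0.50, by = 0.01), nRand = 100L,
                      nRealizations = 1e6, seed, alpha = 0.05, bands = 1:4,
                      boundary = "periodic", scrub = TRUE, clinical = TRUE,
                      globalCurves = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(cohort)) {
    if (is.null(manifest)) stop("either manifest or cohort must be given")
    if (!file.exists(manifest)) stop("manifest does not exist: ", manifest)
  }
  stopifnot(all(densities > 0), all(densities <= 1),
            !is.unsorted(densities, strictly = TRUE),
            all(bands %in% 1:4), alpha > 0, alpha < 1)
  structure(list(manifest = manifest, cohort = cohort, outDir = outDir,
                 densities = densities, nRand = as.integer(nRand),
                 nRealizations = nRealizations, seed = as.integer(seed),
                 alpha = alpha, bands = as.integer(bands),
                 boundary = boundary, scrub = scrub, clinical = clinical,
                 globalCurves = globalCurves),
            class = "fbandnetConfig")
}

#' Load a run configuration from a YAML file
#'
#' The YAML maps directly onto [runConfig()] arguments; relative manifest
#' paths are resolved against the YAML's directory.
#'
#' @param path YAML config file.
#' @return Validated config list of class \code{fbandnetConfig}.
#' @export
readRunConfig <- function(path) {
  args <- yaml::read_yaml(path)
  unknown <- setdiff(names(args), names(formals(runConfig)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(args$manifest) && !file.exists(args$manifest))
    args$manifest <- file.path(dirname(path), args$manifest)
  do.call(runConfig, args)
}

#' Read a cohort manifest
#'
#' Loads the manifest JSON written by [writeCohort()] and the per-session
#' TSV files it lists, pairing pre and post sessions by subject. Subjects
#' missing either session are dropped with a warning.
#'
#' @param path manifest path.
#' @return List with elements \code{pre}, \code{post} (lists of
#'   [RoiTimeseries-class]) and \code{tr}.
#' @export
readManifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(man$sessions) || !NROW(man$sessions))
    stop("empty manifest: no sessions listed")
  ses <- as.data.frame(man$sessions)
  need <- c("subject", "session", "file")
  if (!all(need %in% names(ses)))
    stop("malformed manifest: sessions need fields subject, session, file")
  dirn <- dirname(path)
  subjects <- unique(ses$subject)
  pre <- list(); post <- list()
  for (s in subjects) {
    rows <- ses[ses$subject == s, ]
    if (!all(c("pre", "post") %in% rows$session)) {
      warning(sprintf("subject %s missing a session; dropped", s))
      next
    }
    for (sess in c("pre", "post")) {
      f <- file.path(dirn, rows$file[rows$session == sess][1])
      ts <- readRoiTimeseries(f, tr = man$tr, subjectId = s, session = sess)
      if (sess == "pre") pre[[length(pre) + 1L]] <- ts
      else post[[length(post) + 1L]] <- ts
    }
  }
  if (!length(pre)) stop("no complete subject pairs in manifest")
  list(pre = pre, post = post, tr = man$tr)
}

# AUCs of several nodal metrics across a density stack: nodal metrics are
# computed once per graph and averaged over the grid. Returns nodes x
# metrics.
.nodalAucs <- function(stack, metrics) {
  nms <- lapply(stack@graphs, nodalMetrics)
  n <- nrow(nms[[1]])
  vapply(metrics, function(m)
    rowMeans(vapply(nms, function(df) df[[m]], numeric(n))), numeric(n))
}

#' Run the full frequency-resolved network analysis
#'
#' Executes, per subject and session: wavelet band decomposition, per-band
#' connectivity over retained volumes, density thresholding, topological
#' metrics and their AUC over the density grid; then, per band: paired
#' sign-permutation tests on every connection and every nodal-metric AUC
#' (with Cohen's d and power), Bonferroni thresholds, FDR subnetworks, and
#' optional exploratory clinical regressions. All tables are written to
#' \code{config$outDir} as TSV plus a JSON summary with provenance; rerunning
#' with the same config and seed reproduces the summary byte for byte.
#'
#' @param config a config from [runConfig()].
#' @return Invisibly, the report bundle: list with \code{edgeTests},
#'   \code{nodalTests} (per band), \code{subnetworks}, \code{globalCurves},
#'   \code{clinical}, \code{summaryPath}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "fbandnetConfig"))
  if (!is.null(config$cohort)) {
    pre <- config$cohort@pre
    post <- config$cohort@post
    clin <- config$cohort@clinical
  } else {
    loaded <- readManifest(config$manifest)
    pre <- loaded$pre; post <- loaded$post
    clin <- NULL
    cdir <- file.path(dirname(config$manifest), "clinical.tsv")
    if (file.exists(cdir)) clin <- utils::read.delim(cdir)
  }
  nSubj <- length(pre)
  nReg <- nrow(pre[[1]]@data)
  labels <- pre[[1]]@regionLabels
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  nodalMetricNames <- c("clustering", "localEfficiency", "degree",
                        "betweenness", "participation", "withinModuleZ")
  pairs <- .edgePairs(nReg)

  # per subject/session/band: connectivity and nodal AUCs
  conn <- list(pre = list(), post = list())
  nodalAuc <- list(pre = list(), post = list())
  for (sess in c("pre", "post")) {
    series <- if (sess == "pre") pre else post
    for (s in seq_len(nSubj)) {
      ts <- series[[s]]
      if (!config$scrub) ts@scrubMask <- NULL
      bs <- sdwtDecompose(ts, boundary = config$boundary)
      for (b in config$bands) {
        C <- bandConnectivity(bs, b, subjectId = ts@subjectId,
                              session = sess)
        conn[[sess]][[sprintf("b%d_s%d", b, s)]] <- C
        stack <- densityGraphStack(C, config$densities)
        nodalAuc[[sess]][[sprintf("b%d_s%d", b, s)]] <-
          .nodalAucs(stack, nodalMetricNames)
      }
    }
  }

  edgeTests <- list(); nodalTests <- list(); subnetworks <- list()
  globalCurvesOut <- list()
  for (b in config$bands) {
    key <- function(s, sess) conn[[sess]][[sprintf("b%d_s%d", b, s)]]
    preE <- t(vapply(seq_len(nSubj),
                     function(s) edgeVector(key(s, "pre")), numeric(nrow(pairs))))
    postE <- t(vapply(seq_len(nSubj),
                      function(s) edgeVector(key(s, "post")), numeric(nrow(pairs))))
    et <- pairedPermutationTests(preE, postE, config$nRealizations,
                                 seed = config$seed + b)
    et <- cbind(data.frame(i = pairs[, 1], j = pairs[, 2],
                           region_i = labels[pairs[, 1]],
                           region_j = labels[pairs[, 2]]), et)
    edgeTests[[as.character(b)]] <- et
    subnetworks[[as.character(b)]] <-
      buildFdrSubnetwork(et, band = b, alpha = config$alpha,
                         nRegions = nReg, regionLabels = labels)

    nt <- list()
    for (m in nodalMetricNames) {
      preM <- t(vapply(seq_len(nSubj), function(s)
        nodalAuc[["pre"]][[sprintf("b%d_s%d", b, s)]][, m], numeric(nReg)))
      postM <- t(vapply(seq_len(nSubj), function(s)
        nodalAuc[["post"]][[sprintf("b%d_s%d", b, s)]][, m], numeric(nReg)))
      r <- pairedPermutationTests(preM, postM, config$nRealizations,
                                  seed = config$seed + 10L * b)
      nt[[m]] <- cbind(data.frame(region = labels, metric = m), r)
    }
    nodalTests[[as.character(b)]] <- do.call(rbind, nt)

    if (config$globalCurves) {
      curves <- lapply(c("pre", "post"), function(sess) {
        cs <- lapply(seq_len(nSubj), function(s) {
          stack <- densityGraphStack(key(s, sess), config$densities)
          metricCurves(stack, metrics = c("Cnet", "Lnet", "Cnorm", "sigma"),
                       nRand = config$nRand,
                       seed = config$seed + 100L * b + s)
        })
        sapply(c("Cnet", "Lnet", "Cnorm", "sigma"), function(m)
          rowMeans(vapply(cs, function(x) x[[m]]@values,
                          numeric(length(config$densities)))))
      })
      names(curves) <- c("pre", "post")
      globalCurvesOut[[as.character(b)]] <- curves
    }
  }

  clinicalOut <- NULL
  if (config$clinical && !is.null(clin) && "change" %in% names(clin)) {
    feats <- lapply(config$bands, function(b) {
      sn <- subnetworks[[as.character(b)]]
      if (!nrow(sn@edges)) return(NULL)
      idx <- cbind(sn@edges$i, sn@edges$j)
      f <- vapply(seq_len(nSubj), function(s)
        mean(conn[["post"]][[sprintf("b%d_s%d", b, s)]]@values[idx] -
             conn[["pre"]][[sprintf("b%d_s%d", b, s)]]@values[idx]),
        numeric(1))
      covs <- clin[, intersect(c("age", "sex", "iq"), names(clin)),
                   drop = FALSE]
      fit <- regressOutcome(f, clin$change,
                            covariates = if (ncol(covs)) covs else NULL)
      data.frame(band = b, slope = fit$slope, p = fit$p, n = fit$n,
                 note = "exploratory; uncorrected for multiple comparisons")
    })
    clinicalOut <- do.call(rbind, feats)
  }

  # write the report bundle
  for (b in names(edgeTests)) {
    utils::write.table(edgeTests[[b]],
      file.path(config$outDir, sprintf("edge_tests_band%s.tsv", b)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nodalTests[[b]],
      file.path(config$outDir, sprintf("nodal_tests_band%s.tsv", b)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sn <- subnetworks[[b]]
    utils::write.table(sn@edges,
      file.path(config$outDir, sprintf("subnetwork_edges_band%s.tsv", b)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(region = names(sn@withinSubnetworkDegree),
                 degree = sn@withinSubnetworkDegree),
      file.path(config$outDir, sprintf("subnetwork_degree_band%s.tsv", b)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(clinicalOut))
    utils::write.table(clinicalOut, file.path(config$outDir, "clinical_regressions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfgForHash <- config[setdiff(names(config), c("cohort", "outDir"))]
  summary <- list(
    schema = "fbandnet-summary-1",
    version = as.character(utils::packageVersion("fbandnet")),
    seed = config$seed,
    config_hash = .configHash(cfgForHash),
    n_subjects = nSubj,
    n_regions = nReg,
    bands = config$bands,
    bonferroni_regions = bonferroniThreshold(config$alpha, nReg),
    bonferroni_edges = bonferroniThreshold(config$alpha, nrow(pairs)),
    p_resolution = permutationResolution(config$nRealizations, nSubj),
    subnetwork_sizes = vapply(subnetworks, function(s) nrow(s@edges),
                              integer(1)))
  summaryPath <- file.path(config$outDir, "summary.json")
  jsonlite::write_json(summary, summaryPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(edgeTests = edgeTests, nodalTests = nodalTests,
                 subnetworks = subnetworks, globalCurves = globalCurvesOut,
                 clinical = clinicalOut, summaryPath = summaryPath))
}
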