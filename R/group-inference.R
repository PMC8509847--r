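# All 2^n sign assignments as a (2^n x n) matrix of +/-1.
.signMatrix <- function(n) {
  stopifnot(n <= 25)
  m <- 2^n
  S <- matrix(-1, m, n)
  idx <- 0:(m - 1)
  for (j in seq_len(n))
    S[bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0, j] <- 1
  S
}

#' Achievable resolution of a sign-permutation p-value
#'
#' With N sampled realizations the empirical tail probability cannot resolve
#' differences below 1/N; with n paired subjects the 2^n possible sign
#' assignments cap the resolution at 2^-n regardless of how many
#' realizations are drawn (at n = 12, 2^-12 = 0.0002441).
#'
#' @param nRealizations number of realizations.
#' @param nSubjects optional number of paired subjects.
#' @return The coarser of the two limits when both apply.
#' @export
permutationResolution <- function(nRealizations, nSubjects = NULL) {
  r <- 1 / nRealizations
  if (!is.null(nSubjects)) r <- max(r, 2^-nSubjects)
  r
}

#' Cohen's d with pooled standard deviation
#'
#' \eqn{d = (\bar{x}_{post} - \bar{x}_{pre}) / s_p} with \eqn{s_p} pooled
#' over the two sessions' sample variances with n - 1 weights. Negative d
#' means a decrease after treatment.
#'
#' @param pre,post per-subject values (each length >= 2).
#' @return Scalar effect size.
#' @export
cohensDPooled <- function(pre, post) {
  n1 <- length(pre); n2 <- length(post)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(pre) + (n2 - 1) * stats::var(post)) /
               (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled standard deviation: effect size undefined")
  (mean(post) - mean(pre)) / sp
}

#' Power of the two-sided one-sample t-test
#'
#' Power at level \code{alpha} against the point alternative given by the
#' observed mean and standard deviation of the paired changes, tested
#' against \eqn{\mu_0 = 0}: noncentral-t with noncentrality
#' \eqn{\sqrt{n}\,\bar{d}/s} and n - 1 degrees of freedom.
#'
#' @param diffs per-subject paired changes (length >= 2).
#' @param alpha significance level (default 0.05).
#' @return Power in [alpha, 1].
#' @export
powerOneSample <- function(diffs, alpha = 0.05) {
  n <- length(diffs)
  stopifnot(n >= 2)
  s <- stats::sd(diffs)
  m <- mean(diffs)
  if (s == 0) return(if (m != 0) 1 else alpha)
  ncp <- sqrt(n) * m / s
  tc <- stats::qt(1 - alpha / 2, df = n - 1)
  # pt() warns about precision at extreme noncentrality, where power is
  # saturated at 0/1 far beyond any reported digit
  suppressWarnings(
    1 - stats::pt(tc, df = n - 1, ncp = ncp) +
      stats::pt(-tc, df = n - 1, ncp = ncp))
}

#' Paired sign-permutation test
#'
#' Tests a change D (mean of post - pre) against the null of no treatment
#' effect by randomly reassigning a positive or negative sign to each
#' subject's difference and recomputing the average difference D' for each
#' realization. The p-value is the empirical probability that D' is at least
#' as extreme as D in the direction of \code{sign(D)} (one-sided tail). When
#' \eqn{2^n \le} \code{nRealizations} all sign assignments are enumerated,
#' making the test exact; the observed assignment is part of the null set,
#' so p is never 0 and every exhaustive p is a multiple of \eqn{2^{-n}}
#' (0.0002441 at n = 12). For larger n, seeded Monte Carlo sampling is used
#' and the observed assignment counts as one realization.
#'
#' @param pre per-subject pre-treatment values, or the paired differences
#'   when \code{post} is \code{NULL}.
#' @param post per-subject post-treatment values (same order), or
#'   \code{NULL}.
#' @param nRealizations realization budget (default 1e6; n = 12 then always
#'   enumerates its 4096 assignments exactly).
#' @param seed integer seed (used only when sampling).
#' @param alpha level at which test power is evaluated.
#' @return A [PermutationResult-class].
#' @examples
#' res <- signPermutationTest(rep(0, 12), rep(1, 12))
#' res@p  # 1/4096: only the all-positive assignment is as extreme
#' @export
signPermutationTest <- function(pre, post = NULL, nRealizations = 1e6,
                                seed = 1L, alpha = 0.05) {
  if (is.null(post)) {
    diffs <- pre
    d <- NA_real_
  } else {
    stopifnot(length(pre) == length(post))
    diffs <- post - pre
    d <- if (stats::sd(pre) == 0 && stats::sd(post) == 0) NA_real_
         else cohensDPooled(pre, post)
  }
  n <- length(diffs)
  stopifnot(n >= 2)
  D <- mean(diffs)
  pw <- if (stats::sd(diffs) == 0) (if (D != 0) 1 else alpha)
        else powerOneSample(diffs, alpha)
  if (all(diffs == 0))
    return(new("PermutationResult", observedD = 0, p = 1,
               nRealizations = 2^n, exhaustive = TRUE,
               effectSizeD = if (is.na(d)) 0 else d, power = pw))
  exhaustive <- 2^n <= nRealizations
  if (exhaustive) {
    Dp <- drop(.signMatrix(n) %*% diffs) / n
    p <- if (D >= 0) mean(Dp >= D - 1e-12 * max(1, abs(D)))
         else mean(Dp <= D + 1e-12 * max(1, abs(D)))
    nr <- 2^n
  } else {
    set.seed(seed)
    nr <- nRealizations
    hits <- 1  # the observed assignment
    done <- 1
    block <- 250000L
    while (done < nr) {
      b <- min(block, nr - done)
      S <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
      Dp <- drop(S %*% diffs) / n
      hits <- hits + if (D >= 0) sum(Dp >= D - 1e-12 * max(1, abs(D)))
                     else sum(Dp <= D + 1e-12 * max(1, abs(D)))
      done <- done + b
    }
    p <- hits / nr
  }
  new("PermutationResult", observedD = D, p = p, nRealizations = nr,
      exhaustive = exhaustive, effectSizeD = d, power = pw)
}

#' Sign-permutation tests for many features at once
#'
#' Vectorized version of [signPermutationTest()] for a subjects-by-features
#' pair of matrices (e.g., all 2850 connections of one band): one exhaustive
#' enumeration (or one sampled realization set) is shared across features.
#'
#' @param preMat,postMat numeric matrices, subjects x features, same shape.
#' @param nRealizations,seed,alpha as in [signPermutationTest()].
#' @return data.frame with one row per feature: \code{observedD}, \code{p},
#'   \code{effectSizeD}, \code{power}, \code{exhaustive},
#'   \code{nRealizations}.
#' @export
pairedPermutationTests <- function(preMat, postMat, nRealizations = 1e6,
                                   seed = 1L, alpha = 0.05) {
  stopifnot(identical(dim(preMat), dim(postMat)))
  n <- nrow(preMat)
  m <- ncol(preMat)
  Dmat <- postMat - preMat
  D <- colMeans(Dmat)
  tol <- 1e-12 * pmax(1, abs(D))
  exhaustive <- 2^n <= nRealizations
  if (exhaustive) {
    Dp <- .signMatrix(n) %*% Dmat / n   # 2^n x m
    hi <- colMeans(Dp >= rep(D - tol, each = nrow(Dp)))
    lo <- colMeans(Dp <= rep(D + tol, each = nrow(Dp)))
    p <- ifelse(D >= 0, hi, lo)
    nr <- 2^n
  } else {
    set.seed(seed)
    nr <- nRealizations
    hits <- rep(1, m)
    done <- 1
    block <- max(1L, as.integer(2.5e7 / m))
    while (done < nr) {
      b <- min(block, nr - done)
      S <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
      Dp <- S %*% Dmat / n
      hi <- colSums(Dp >= rep(D - tol, each = b))
      lo <- colSums(Dp <= rep(D + tol, each = b))
      hits <- hits + ifelse(D >= 0, hi, lo)
      done <- done + b
    }
    p <- hits / nr
  }
  p[apply(Dmat == 0, 2, all)] <- 1
  sdPre <- apply(preMat, 2, stats::sd)
  sdPost <- apply(postMat, 2, stats::sd)
  sp <- sqrt(((n - 1) * sdPre^2 + (n - 1) * sdPost^2) / (2 * n - 2))
  d <- ifelse(sp > 0, (colMeans(postMat) - colMeans(preMat)) / sp, NA_real_)
  sdD <- apply(Dmat, 2, stats::sd)
  pw <- numeric(m)
  ok <- sdD > 0
  if (any(ok)) {
    ncp <- sqrt(n) * D[ok] / sdD[ok]
    tc <- stats::qt(1 - alpha / 2, df = n - 1)
    pw[ok] <- suppressWarnings(
      1 - stats::pt(tc, df = n - 1, ncp = ncp) +
        stats::pt(-tc, df = n - 1, ncp = ncp))
  }
  pw[!ok] <- ifelse(D[!ok] != 0, 1, alpha)
  data.frame(observedD = D, p = p, effectSizeD = d, power = pw,
             exhaustive = exhaustive, nRealizations = nr)
}

#' Bonferroni threshold
#'
#' Per-comparison significance threshold \code{alpha / m} for a family of m
#' comparisons: 0.05/76 = 0.00066 for 76 regional metrics, 0.05/2850 =
#' 1.75e-5 for 2850 connections.
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons.
#' @return Scalar threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) alpha / m

#' Benjamini-Hochberg FDR selection
#'
#' Standard step-up procedure at level \code{alpha}: sort the p-values
#' ascending, find the largest k with \eqn{p_{(k)} \le k \alpha / m}, and
#' select everything with \eqn{p \le p_{(k)}}. Implemented through
#' \code{stats::p.adjust(method = "BH")}, whose adjusted values are at most
#' \code{alpha} exactly for the step-up selection set.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return Integer indices of the selected hypotheses (empty when none).
#' @export
bhFdrSelect <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) return(integer(0))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  which(stats::p.adjust(pvals, method = "BH") <= alpha)
}

#' FDR subnetwork of significantly changed connections
#'
#' Applies Benjamini-Hochberg selection at level \code{alpha} to the per-edge
#' sign-permutation p-values of one frequency band and assembles the
#' surviving connections into a subnetwork. The within-subnetwork nodal
#' degree counts, for every region, the selected connections incident to it
#' (how broadly the treatment effect touches that region's communication).
#'
#' @param edgeTests data.frame with one row per connection: columns \code{i},
#'   \code{j} (region indices), \code{p}, and \code{observedD} (sign gives
#'   the direction of change).
#' @param band frequency band index stored in the result.
#' @param alpha FDR level (default 0.05).
#' @param nRegions total number of regions (defaults to \code{max(i, j)}).
#' @param regionLabels optional region names for the degree vector.
#' @return A [Subnetwork-class].
#' @export
buildFdrSubnetwork <- function(edgeTests, band = 1L, alpha = 0.05,
                               nRegions = NULL, regionLabels = NULL) {
  stopifnot(all(c("i", "j", "p", "observedD") %in% names(edgeTests)))
  if (is.null(nRegions)) nRegions <- max(edgeTests$i, edgeTests$j)
  sel <- bhFdrSelect(edgeTests$p, alpha)
  edges <- data.frame(
    i = edgeTests$i[sel], j = edgeTests$j[sel], p = edgeTests$p[sel],
    direction = ifelse(edgeTests$observedD[sel] >= 0, 1L, -1L))
  deg <- as.integer(tabulate(c(edges$i, edges$j), nbins = nRegions))
  names(deg) <- if (!is.null(regionLabels)) regionLabels else
    sprintf("R%02d", seq_len(nRegions))
  new("Subnetwork", band = as.integer(band), alpha = alpha, edges = edges,
      withinSubnetworkDegree = deg)
}
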