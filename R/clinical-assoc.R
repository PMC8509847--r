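#' Regress a clinical outcome on a network feature
#'
#' Ordinary least squares of \code{outcome} on an intercept, the network
#' feature, and optional covariates (e.g., age, sex, IQ, which are thereby
#' partialed out of the reported feature effect). Subjects with a missing
#' outcome or feature are dropped listwise. With covariates present the
#' returned slope equals, by the Frisch-Waugh-Lovell identity, the slope of
#' the residualized outcome on the residualized feature.
#'
#' These regressions are exploratory: no multiple-testing correction is
#' applied here, and callers should label results accordingly.
#'
#' @param feature per-subject network feature values (the main regressor).
#' @param outcome per-subject clinical values (e.g., change in total score).
#' @param covariates optional numeric matrix or data.frame, subjects x k.
#' @param minN minimum complete cases required (default 4).
#' @return List with \code{slope}, \code{p} (two-sided t-test on the feature
#'   coefficient), \code{n} (complete cases used), \code{fit} (the
#'   underlying \code{lm}).
#' @export
regressOutcome <- function(feature, outcome, covariates = NULL, minN = 4L) {
  stopifnot(length(feature) == length(outcome))
  df <- data.frame(.outcome = outcome, .feature = feature)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(feature))
    names(covariates) <- paste0("c_", seq_len(ncol(covariates)))
    df <- cbind(df, covariates)
  }
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < minN)
    stop(sprintf("only %d complete cases; need at least %d", nrow(df), minN))
  X <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[setdiff(seq_len(ncol(X)),
                               qrX$pivot[seq_len(qrX$rank)])]
    stop(sprintf("collinear design; dependent column(s): %s",
                 paste(dep, collapse = ", ")))
  }
  fit <- stats::lm(.outcome ~ ., data = df)
  co <- summary(fit)$coefficients
  list(slope = co[".feature", "Estimate"],
       p = co[".feature", "Pr(>|t|)"],
       n = nrow(df), fit = fit)
}
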