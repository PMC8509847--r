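# Nearest correlation matrix by eigenvalue clipping: clip negative
# eigenvalues to a small floor, then rescale to unit diagonal. One or two
# passes are enough for the mildly indefinite matrices that arise from
# planting effects or leakage compensation.
.nearestCorrelation <- function(S, floor = 1e-8, maxit = 10L) {
  for (it in seq_len(maxit)) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) >= floor && max(abs(diag(S) - 1)) < 1e-12) break
    vals <- pmax(e$values, floor)
    S <- e$vectors %*% (vals * t(e$vectors))
    d <- 1 / sqrt(diag(S))
    S <- S * tcrossprod(d)
    S <- (S + t(S)) / 2
    diag(S) <- 1
  }
  S
}

.isPsd <- function(S, tol = -1e-8) {
  min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) >= tol
}

#' Region labels of the 76-region Desikan-Killiany parcellation
#'
#' Left/right pairs of the 38 cortical and subcortical regions of interest,
#' in standard order, as short abbreviations prefixed with \code{L_} /
#' \code{R_}.
#'
#' @return Character vector of 76 labels.
#' @export
dkRegionLabels <- function() {
  abbr <- c("BANK", "CauACC", "CauMFG", "CUN", "FFG", "IPC", "ITG", "ICC",
            "LatOC", "LatOFC", "LING", "MedOFC", "MTG", "PHG", "PCL",
            "ParsOPE", "ParsORB", "ParsTRI", "PCAL", "PoCG", "PCC", "PreCG",
            "PCUN", "RosACC", "RosMFG", "SFG", "SPC", "STG", "SMG", "TTC",
            "INS", "THA", "CAU", "PUT", "PAL", "HIP", "AMYG", "ACCU")
  c(paste0("L_", abbr), paste0("R_", abbr))
}
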