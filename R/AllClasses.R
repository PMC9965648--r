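#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Repeated-measures metabolite panel
#'
#' A `MetabolitePanel` holds quantified metabolite concentrations for N
#' individuals measured at T ordered time points, one assay matrix per
#' metabolite. It extends [SummarizedExperiment::SummarizedExperiment] with
#' individuals as rows (covariates in `rowData`) and time points as columns.
#' `NA` cells mark missing measurements; every individual must retain at
#' least two observed time points for every metabolite, otherwise the object
#' is invalid and should be filtered at load time (see [readWideCsv()]).
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("MetabolitePanel", contains = "SummarizedExperiment")

setValidity("MetabolitePanel", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assays(object)
  if (length(a) == 0L) msg <- c(msg, "panel has no metabolite assays")
  if (is.null(rownames(object))) msg <- c(msg, "individual ids (rownames) are required")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicated individual ids")
  if (is.null(colnames(object))) msg <- c(msg, "time labels (colnames) are required")
  for (m in names(a)) {
    v <- a[[m]]
    if (!is.numeric(v)) {
      msg <- c(msg, sprintf("assay '%s' is not numeric", m))
      next
    }
    if (any(!is.finite(v) & !is.na(v)))
      msg <- c(msg, sprintf("assay '%s' contains non-finite observed values", m))
    nobs <- rowSums(!is.na(v))
    if (ncol(v) >= 2L && any(nobs < 2L))
      msg <- c(msg, sprintf(
        "individuals with <2 observed time points for '%s': %s", m,
        paste(rownames(object)[nobs < 2L], collapse = ", ")))
  }
  cv <- SummarizedExperiment::rowData(object)
  if (ncol(cv) > 0L) {
    num <- vapply(seq_len(ncol(cv)), function(j) is.numeric(cv[[j]]), logical(1))
    if (!all(num))
      msg <- c(msg, sprintf("non-numeric covariate columns (encode categoricals as indicators): %s",
                            paste(colnames(cv)[!num], collapse = ", ")))
    else if (anyNA(as.matrix(cv)))
      msg <- c(msg, "missing covariate values are not permitted")
  }
  if (length(msg)) msg else TRUE
})

#' Posterior draws from the random-intercept model
#'
#' Retained, thinned MCMC draws of the fixed effects, variance components and
#' per-individual random intercepts, organised by chain. Dimensions are
#' draws-within-chain x parameter x chain.
#'
#' @slot beta0 numeric matrix, draws x chains.
#' @slot beta1 numeric array, draws x L x chains (L covariates; may have L = 0).
#' @slot sigma2S numeric matrix, draws x chains; individual-effect variance.
#' @slot sigma2Eps numeric matrix, draws x chains; residual variance.
#' @slot s numeric array, draws x N x chains; per-individual intercepts.
#' @slot individualIds character, length N.
#' @slot covariateNames character, length L.
#' @slot config list echoing the [mcmcConfig()] used for the fit.
#' @export
setClass("PosteriorSamples",
  representation(beta0 = "matrix", beta1 = "array", sigma2S = "matrix",
                 sigma2Eps = "matrix", s = "array", individualIds = "character",
                 covariateNames = "character", config = "list"))

setValidity("PosteriorSamples", function(object) {
  msg <- character()
  nd <- nrow(object@beta0)
  nc <- ncol(object@beta0)
  if (any(object@sigma2S <= 0) || any(object@sigma2Eps <= 0))
    msg <- c(msg, "variance draws must be strictly positive")
  dims_ok <- nrow(object@sigma2S) == nd && nrow(object@sigma2Eps) == nd &&
    dim(object@beta1)[1] == nd && dim(object@s)[1] == nd &&
    ncol(object@sigma2S) == nc && ncol(object@sigma2Eps) == nc &&
    dim(object@beta1)[3] == nc && dim(object@s)[3] == nc
  if (!dims_ok) msg <- c(msg, "all chains must have equal numbers of retained draws")
  if (dim(object@s)[2] != length(object@individualIds))
    msg <- c(msg, "s draws do not match individual ids")
  if (dim(object@beta1)[2] != length(object@covariateNames))
    msg <- c(msg, "beta1 draws do not match covariate names")
  if (length(msg)) msg else TRUE
})

#' Cell-level posterior-predictive intervals and flags
#'
#' One row per observed (individual, time point) cell of one metabolite:
#' posterior-predictive HPD and central interval endpoints, the observed
#' value, and the flag. The raw predictive draws are kept (cells x draws)
#' so intervals can be recomputed at a different W.
#'
#' @slot cells a [S4Vectors::DataFrame] with columns `individual`, `time`,
#'   `metabolite`, `observed`, `hpdLower`, `hpdUpper`, `centralLower`,
#'   `centralUpper`, `flagged`.
#' @slot draws numeric matrix, cells x predictive draws.
#' @slot W numeric scalar in (0, 100); the interval mass in percent.
#' @export
setClass("FlagTable",
  representation(cells = "DataFrame", draws = "matrix", W = "numeric"))

setValidity("FlagTable", function(object) {
  msg <- character()
  need <- c("individual", "time", "metabolite", "observed", "hpdLower",
            "hpdUpper", "centralLower", "centralUpper", "flagged")
  if (!all(need %in% colnames(object@cells)))
    msg <- c(msg, paste("cells must have columns:", paste(need, collapse = ", ")))
  if (length(object@W) != 1L || object@W <= 0 || object@W >= 100)
    msg <- c(msg, "W must be a single percentage in (0, 100)")
  if (nrow(object@draws) > 0L && nrow(object@draws) != nrow(object@cells))
    msg <- c(msg, "draws must have one row per cell")
  if (all(need %in% colnames(object@cells)) && nrow(object@cells) > 0L) {
    cc <- object@cells
    done <- !is.na(cc$hpdLower)
    if (any(done & (cc$hpdLower >= cc$hpdUpper)))
      msg <- c(msg, "hpdLower must be < hpdUpper")
    bad <- done & !is.na(cc$observed) &
      (cc$flagged != (cc$observed < cc$hpdLower | cc$observed > cc$hpdUpper))
    if (any(bad)) msg <- c(msg, "flag inconsistent with HPD interval")
    if (any(done & is.na(cc$observed) & cc$flagged))
      msg <- c(msg, "cells without an observed value must not be flagged")
  }
  if (length(msg)) msg else TRUE
})

#' Gelman-Rubin convergence report
#'
#' Potential scale reduction factors for the monitored model parameters
#' (intercept, each covariate coefficient, and the two variance components),
#' with their mean and standard deviation and an overall pass indicator
#' (all values inside the conventional 0.9-1.05 window).
#'
#' @slot psrf named numeric vector of per-parameter PSRF values.
#' @slot mean numeric scalar, mean PSRF over parameters.
#' @slot sd numeric scalar, standard deviation over parameters.
#' @slot pass logical scalar.
#' @export
setClass("PsrfReport",
  representation(psrf = "numeric", mean = "numeric", sd = "numeric",
                 pass = "logical"))
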