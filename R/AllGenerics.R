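#' @rdname MetabolitePanel-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname MetabolitePanel-accessors
#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))

#' @rdname MetabolitePanel-accessors
#' @export
setGeneric("metaboliteNames", function(x) standardGeneric("metaboliteNames"))

#' @rdname MetabolitePanel-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname MetabolitePanel-accessors
#' @export
setGeneric("metaboliteValues", function(x, metabolite) standardGeneric("metaboliteValues"))

#' @rdname MetabolitePanel-accessors
#' @export
setGeneric("observedMask", function(x, metabolite) standardGeneric("observedMask"))

#' @rdname fitBglm
#' @export
setGeneric("fitBglm", function(y, X, prior = priorSpec(), cfg = mcmcConfig(), ...)
  standardGeneric("fitBglm"))

#' @rdname FlagTable-accessors
#' @export
setGeneric("flaggedCells", function(x) standardGeneric("flaggedCells"))

#' @rdname FlagTable-accessors
#' @export
setGeneric("predictiveDraws", function(x) standardGeneric("predictiveDraws"))
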