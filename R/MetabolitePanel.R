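#' Construct a MetabolitePanel
#'
#' Bundles metabolite concentration matrices (individuals x time points, one
#' matrix per metabolite, `NA` for missing cells) with a per-individual
#' covariate table into a single validated container.
#'
#' @param assays named list of numeric N x T matrices, one per metabolite,
#'   all with identical dimensions. A single matrix is accepted and must be
#'   named via `metabolite`.
#' @param covariates data.frame or DataFrame of numeric covariates, one row
#'   per individual in the same order as the assay rows. Categorical
#'   covariates must be indicator-encoded beforehand (see [readWideCsv()]).
#' @param individualIds,timeLabels character vectors; default to the
#'   dimnames of the first assay.
#' @param metabolite name used when `assays` is a single unnamed matrix.
#'
#' @return A [MetabolitePanel-class] object.
#' @examples
#' y <- matrix(rnorm(8, 100, 5), 2, 4,
#'             dimnames = list(c("A", "B"), paste0("T", 1:4)))
#' panel <- MetabolitePanel(list(Ala = y),
#'                          covariates = data.frame(age = c(30, 40)))
#' metaboliteValues(panel, "Ala")
#' @export
MetabolitePanel <- function(assays, covariates = NULL, individualIds = NULL,
                            timeLabels = NULL, metabolite = "metabolite") {
  if (is.matrix(assays)) assays <- stats::setNames(list(assays), metabolite)
  if (is.null(names(assays)) || any(!nzchar(names(assays))))
    stop("every assay must be named after its metabolite")
  if (is.null(individualIds)) individualIds <- rownames(assays[[1]])
  if (is.null(individualIds)) individualIds <- paste0("ind", seq_len(nrow(assays[[1]])))
  if (is.null(timeLabels)) timeLabels <- colnames(assays[[1]])
  if (is.null(timeLabels)) timeLabels <- paste0("T", seq_len(ncol(assays[[1]])))
  assays <- lapply(assays, function(v) {
    dimnames(v) <- list(individualIds, timeLabels)
    v
  })
  if (is.null(covariates))
    covariates <- S4Vectors::DataFrame(row.names = individualIds)
  else {
    covariates <- S4Vectors::DataFrame(covariates, row.names = individualIds)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = covariates)
  colnames(se) <- timeLabels
  methods::new("MetabolitePanel", se)
}

#' Accessors for MetabolitePanel objects
#'
#' @param x a [MetabolitePanel-class].
#' @param metabolite metabolite name; defaults to the first assay.
#' @return `individualIds`, `timeLabels` and `metaboliteNames` return
#'   character vectors; `covariates` returns the numeric covariate matrix
#'   (N x L, possibly zero columns); `metaboliteValues` returns the N x T
#'   concentration matrix and `observedMask` the matching logical matrix.
#' @name MetabolitePanel-accessors
NULL

#' @rdname MetabolitePanel-accessors
#' @export
setMethod("individualIds", "MetabolitePanel", function(x) rownames(x))

#' @rdname MetabolitePanel-accessors
#' @export
setMethod("timeLabels", "MetabolitePanel", function(x) colnames(x))

#' @rdname MetabolitePanel-accessors
#' @export
setMethod("metaboliteNames", "MetabolitePanel",
          function(x) names(SummarizedExperiment::assays(x)))

#' @rdname MetabolitePanel-accessors
#' @export
setMethod("covariates", "MetabolitePanel", function(x) {
  cv <- SummarizedExperiment::rowData(x)
  m <- as.matrix(as.data.frame(cv))
  if (ncol(cv) == 0L) m <- matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL))
  else rownames(m) <- rownames(x)
  m
})

#' @rdname MetabolitePanel-accessors
#' @export
setMethod("metaboliteValues", "MetabolitePanel", function(x, metabolite) {
  if (missing(metabolite)) metabolite <- metaboliteNames(x)[1]
  SummarizedExperiment::assay(x, metabolite)
})

#' @rdname MetabolitePanel-accessors
#' @export
setMethod("observedMask", "MetabolitePanel", function(x, metabolite) {
  if (missing(metabolite)) metabolite <- metaboliteNames(x)[1]
  !is.na(SummarizedExperiment::assay(x, metabolite))
})

setMethod("show", "MetabolitePanel", function(object) {
  cat("MetabolitePanel:", nrow(object), "individuals x", ncol(object),
      "time points x", length(metaboliteNames(object)), "metabolites\n")
  cat("  metabolites:", paste(utils::head(metaboliteNames(object), 6), collapse = ", "),
      if (length(metaboliteNames(object)) > 6) "..." else "", "\n")
  cv <- SummarizedExperiment::rowData(object)
  cat("  covariates:", if (ncol(cv)) paste(colnames(cv), collapse = ", ") else "(none)", "\n")
  nmiss <- sum(vapply(SummarizedExperiment::assays(object),
                      function(v) sum(is.na(v)), numeric(1)))
  cat("  missing cells:", nmiss, "\n")
})

#' Convert an observed metabolite matrix to (individual, time, value) triples
#'
#' @param panel a [MetabolitePanel-class].
#' @param metabolite metabolite name.
#' @return data.frame with columns `individual`, `time`, `value`, one row per
#'   observed cell, ordered by individual then time.
#' @export
panelTriples <- function(panel, metabolite = metaboliteNames(panel)[1]) {
  v <- metaboliteValues(panel, metabolite)
  obs <- which(!is.na(v), arr.ind = TRUE)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  data.frame(individual = rownames(v)[obs[, 1]],
             time = colnames(v)[obs[, 2]],
             value = v[obs], stringsAsFactors = FALSE)
}
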