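log_msg <- function(..., logFile = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
  invisible(line)
}

encode_covariates <- function(df, logFile = NULL) {
  out <- list()
  for (nm in colnames(df)) {
    col <- df[[nm]]
    if (is.numeric(col)) {
      out[[nm]] <- col
    } else {
      lev <- sort(unique(as.character(col)))
      if (length(lev) < 2L)
        stop("categorical covariate '", nm, "' has a single level")
      log_msg("covariate '", nm, "': indicator-encoded, reference level '",
              lev[1], "'", logFile = logFile)
      for (l in lev[-1]) out[[paste0(nm, ".", l)]] <- as.numeric(col == l)
    }
  }
  as.data.frame(out, check.names = FALSE)
}

#' Read a wide-format repeated-measures CSV
#'
#' Canonical input layout: one row per individual, an id column, covariate
#' columns, and one column per (metabolite, time point) named
#' `<metabolite><sep><timelabel>` (e.g. `Ala_T1`). Empty cells (or
#' `missingToken`) mark missing measurements. Categorical covariates are
#' indicator-encoded against their first (alphabetical) level, which is
#' logged. Individuals with fewer than two observed time points for any
#' metabolite are dropped with a logged message, since the model cannot
#' separate their intra-individual variation from noise.
#'
#' @param path CSV file path.
#' @param idColumn name of the individual-id column (default `"id"`).
#' @param covariateColumns character vector of covariate column names
#'   (default: none).
#' @param sep separator between metabolite name and time label in column
#'   names (default `"_"`; the last occurrence splits).
#' @param missingToken string (besides an empty cell) treated as missing.
#' @param timeOrder optional explicit ordering of time labels; default
#'   lexical.
#' @return a [MetabolitePanel-class].
#' @export
readWideCsv <- function(path, idColumn = "id", covariateColumns = character(),
                        sep = "_", missingToken = "", timeOrder = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty input file: ", path)
  if (!idColumn %in% colnames(df)) stop("id column '", idColumn, "' not found")
  ids <- df[[idColumn]]
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing_cov <- setdiff(covariateColumns, colnames(df))
  if (length(missing_cov))
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  metCols <- setdiff(colnames(df), c(idColumn, covariateColumns))
  if (!length(metCols)) stop("no metabolite columns found")
  # split each column name on the LAST separator occurrence (fixed string)
  pos <- vapply(metCols, function(x) {
    hits <- gregexpr(sep, x, fixed = TRUE)[[1]]
    if (hits[1] == -1L) -1L else hits[length(hits)]
  }, integer(1))
  bad <- pos <= 1L | pos + nchar(sep) > nchar(metCols)
  if (any(bad))
    stop("unparseable metabolite column(s) (expected <metabolite>", sep,
         "<time>): ", paste(metCols[bad], collapse = ", "))
  met <- substr(metCols, 1L, pos - 1L)
  tim <- substr(metCols, pos + nchar(sep), nchar(metCols))
  byMet <- split(tim, met)
  tset <- lapply(byMet, function(x) sort(x))
  if (length(unique(tset)) != 1L)
    stop("metabolites do not share an identical time-label set")
  times <- if (is.null(timeOrder)) tset[[1]] else {
    stopifnot(setequal(timeOrder, tset[[1]]))
    timeOrder
  }
  assays <- lapply(stats::setNames(names(byMet), names(byMet)), function(m) {
    vm <- matrix(NA_real_, nrow(df), length(times),
                 dimnames = list(ids, times))
    for (tl in times) {
      col <- df[[paste0(m, sep, tl)]]
      col[col == missingToken | !nzchar(col)] <- NA
      num <- suppressWarnings(as.numeric(col))
      badCell <- is.na(num) & !is.na(col)
      if (any(badCell))
        stop("non-numeric value(s) in column ", m, sep, tl, ": ",
             paste(unique(col[badCell]), collapse = ", "))
      vm[, tl] <- num
    }
    vm
  })
  # enforce the >=2-observations-per-metabolite rule at load time
  keep <- rep(TRUE, nrow(df))
  for (m in names(assays)) keep <- keep & rowSums(!is.na(assays[[m]])) >= 2L
  if (!all(keep)) {
    log_msg("dropping individual(s) with <2 observed time points: ",
            paste(ids[!keep], collapse = ", "))
    assays <- lapply(assays, function(v) v[keep, , drop = FALSE])
  }
  if (!any(keep)) stop("no individuals with >=2 observed time points remain")
  cov <- NULL
  if (length(covariateColumns)) {
    cov <- df[keep, covariateColumns, drop = FALSE]
    for (nm in covariateColumns) {
      num <- suppressWarnings(as.numeric(cov[[nm]]))
      if (!anyNA(num)) cov[[nm]] <- num
    }
    cov <- encode_covariates(cov)
  }
  MetabolitePanel(assays, covariates = cov, individualIds = ids[keep],
                  timeLabels = times)
}

#' Read a long-format repeated-measures CSV
#'
#' Alternative input: one row per observed cell with columns `individual`,
#' `time`, `metabolite`, `value`, plus an optional separate covariate CSV
#' (id column + covariate columns).
#'
#' @param path long-format CSV path.
#' @param covariatePath optional covariate CSV path.
#' @param idColumn id column name in the covariate file.
#' @return a [MetabolitePanel-class].
#' @export
readLongCsv <- function(path, covariatePath = NULL, idColumn = "id") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("individual", "time", "metabolite", "value")
  if (!all(need %in% colnames(df)))
    stop("long format requires columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty input file: ", path)
  if (anyDuplicated(df[, c("individual", "time", "metabolite")]))
    stop("duplicate (individual, time, metabolite) rows")
  ids <- sort(unique(as.character(df$individual)))
  times <- sort(unique(as.character(df$time)))
  assays <- lapply(split(df, df$metabolite), function(dm) {
    vm <- matrix(NA_real_, length(ids), length(times),
                 dimnames = list(ids, times))
    vm[cbind(as.character(dm$individual), as.character(dm$time))] <- dm$value
    vm
  })
  keep <- rep(TRUE, length(ids))
  for (m in names(assays)) keep <- keep & rowSums(!is.na(assays[[m]])) >= 2L
  if (!all(keep)) {
    log_msg("dropping individual(s) with <2 observed time points: ",
            paste(ids[!keep], collapse = ", "))
    assays <- lapply(assays, function(v) v[keep, , drop = FALSE])
  }
  cov <- NULL
  if (!is.null(covariatePath)) {
    cv <- utils::read.csv(covariatePath, check.names = FALSE)
    if (!idColumn %in% colnames(cv)) stop("id column '", idColumn, "' not found")
    rownames(cv) <- cv[[idColumn]]
    if (!all(ids[keep] %in% rownames(cv)))
      stop("covariate file missing individuals: ",
           paste(setdiff(ids[keep], rownames(cv)), collapse = ", "))
    cov <- encode_covariates(cv[ids[keep], setdiff(colnames(cv), idColumn),
                                drop = FALSE])
  }
  MetabolitePanel(assays, covariates = cov, individualIds = ids[keep],
                  timeLabels = times)
}

#' Write a panel back to the wide CSV layout
#'
#' Inverse of [readWideCsv()] (numeric covariates only); round-trips values
#' exactly via full-precision formatting.
#'
#' @param panel a [MetabolitePanel-class].
#' @param path output path.
#' @param sep metabolite/time separator.
#' @return the path, invisibly.
#' @export
writeWideCsv <- function(panel, path, sep = "_") {
  out <- data.frame(id = individualIds(panel), check.names = FALSE)
  cv <- covariates(panel)
  for (j in seq_len(ncol(cv))) out[[colnames(cv)[j]]] <- cv[, j]
  for (m in metaboliteNames(panel)) {
    v <- metaboliteValues(panel, m)
    for (tl in timeLabels(panel))
      out[[paste0(m, sep, tl)]] <- ifelse(is.na(v[, tl]), "",
                                          sprintf("%.17g", v[, tl]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the result bundle of a flagging run
#'
#' Writes (a) `cells.csv`: one row per observed cell with both interval
#' types, the observed value and the flag; (b) `flag_counts.csv`:
#' per-metabolite, per-time-point flagged-cell counts plus the
#' unique-individual count (an individual flagged at several time points
#' counts once); (c) `psrf.csv`: the convergence report; (d)
#' `manifest.json`: seed, settings and package version, for
#' reproducibility.
#'
#' @param flags a [FlagTable-class] or list of them (one per metabolite).
#' @param psrf a [PsrfReport-class], or `NULL`.
#' @param outDir output directory (created if absent).
#' @param seed,config echoed into the manifest.
#' @return character vector of the files written, invisibly.
#' @export
writeResults <- function(flags, psrf = NULL, outDir, seed = NA_integer_,
                         config = list()) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  if (methods::is(flags, "FlagTable")) flags <- list(flags)
  cells <- do.call(rbind, lapply(flags, function(t) as.data.frame(t@cells)))
  cells <- cells[, c("individual", "time", "metabolite", "observed",
                     "hpdLower", "hpdUpper", "centralLower", "centralUpper",
                     "flagged")]
  f1 <- file.path(outDir, "cells.csv")
  utils::write.csv(cells, f1, row.names = FALSE)
  sm <- summariseFlags(flags, k = 1L)
  counts <- sm$cellCounts
  counts$unique_individuals <- as.integer(sm$uniqueCounts[counts$metabolite])
  f2 <- file.path(outDir, "flag_counts.csv")
  utils::write.csv(counts, f2, row.names = FALSE)
  f3 <- file.path(outDir, "psrf.csv")
  if (!is.null(psrf)) {
    utils::write.csv(data.frame(parameter = c(names(psrf@psrf), "mean", "sd"),
                                psrf = c(psrf@psrf, psrf@mean, psrf@sd),
                                pass = psrf@pass),
                     f3, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(parameter = character(), psrf = numeric(),
                                pass = logical()), f3, row.names = FALSE)
  }
  f4 <- file.path(outDir, "manifest.json")
  manifest <- list(seed = seed, config = config,
                   W = flags[[1]]@W,
                   metabolites = vapply(flags, function(t)
                     as.character(t@cells$metabolite[1]), character(1)),
                   package = "MetaboScreen",
                   version = as.character(utils::packageVersion("MetaboScreen")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, f4, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(f1, f2, f3, f4))
}
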