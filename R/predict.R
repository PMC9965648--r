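#' Partition observed cells into balanced, individual-stratified folds
#'
#' The observed (individual, time point) cells of one metabolite are divided
#' into `nFolds` sub-datasets of as-equal-as-possible size (differing by at
#' most one cell), with each individual's cells placed in distinct folds.
#' Stratification matters: when a cell is held out, the individual's other
#' time points remain in the training data, so the posterior of that
#' individual's random intercept stays informed and the prediction interval
#' is genuinely intra-individual.
#'
#' @param panel a [MetabolitePanel-class].
#' @param metabolite metabolite name.
#' @param nFolds number of folds (default 25, i.e. 4\% of cells per fold for
#'   a complete panel).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return a list of class `FoldAssignment` with elements `nFolds`, `seed`
#'   and `assignment` (data.frame `individual`, `time`, `fold`).
#' @export
makeFolds <- function(panel, metabolite = metaboliteNames(panel)[1],
                      nFolds = 25L, seed = 1L) {
  nFolds <- as.integer(nFolds)
  stopifnot(nFolds >= 2L)
  cells <- panelTriples(panel, metabolite)[, c("individual", "time")]
  if (nrow(cells) < nFolds)
    stop("fewer observed cells (", nrow(cells), ") than folds (", nFolds, ")")
  per_ind <- split(seq_len(nrow(cells)), cells$individual)
  too_many <- vapply(per_ind, length, integer(1)) > nFolds
  if (any(too_many))
    stop("individual(s) with more observed cells than folds: ",
         paste(names(per_ind)[too_many], collapse = ", "))
  set.seed(seed)
  counts <- integer(nFolds)
  fold <- integer(nrow(cells))
  for (ind in sample(names(per_ind))) {
    rows <- per_ind[[ind]]
    k <- length(rows)
    # k least-loaded folds, ties broken randomly; keeps fold sizes within 1
    chosen <- order(counts, sample.int(nFolds))[seq_len(k)]
    fold[rows] <- sample(chosen, k)
    counts[chosen] <- counts[chosen] + 1L
  }
  structure(list(nFolds = nFolds, seed = as.integer(seed),
                 assignment = cbind(cells, fold = fold)),
            class = "FoldAssignment")
}

#' Shortest (highest-density) interval of a set of draws
#'
#' Over the sorted draws, returns the narrowest window containing
#' `ceiling(W/100 * n)` draws; ties in width are broken by the leftmost
#' window so the result is deterministic.
#'
#' @param draws numeric vector of posterior(-predictive) samples.
#' @param W interval mass in percent, 0 < W < 100 (default 95).
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' hpdInterval(1:100, 95)  # [1, 95]: all windows tie, leftmost wins
#' @export
hpdInterval <- function(draws, W = 95) {
  stopifnot(W > 0, W < 100)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  k <- ceiling(W / 100 * n)
  if (k < 2L) stop("too few draws for an interval at W = ", W)
  sorted <- sort(draws)
  widths <- sorted[k:n] - sorted[seq_len(n - k + 1L)]
  j <- which.min(widths)  # leftmost minimum
  c(lower = sorted[j], upper = sorted[j + k - 1L])
}

central_interval <- function(draws, W = 95) {
  al <- (100 - W) / 200
  q <- stats::quantile(draws, c(al, 1 - al), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Cross-validated posterior-predictive draws for every observed cell
#'
#' For each fold, the random-intercept model is refitted with that fold's
#' cells held out of the likelihood, and predictive draws for every held-out
#' cell (i, t) are formed as
#' \deqn{\tilde y = \beta_0 + \sum_l \beta_{1,l} x_{il} + s_i + \epsilon,}
#' taking \eqn{(\beta_0, \beta_1, s_i, \sigma_\epsilon^2)} from each retained
#' posterior draw and drawing \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)}
#' freshly per draw. Each cell therefore receives exactly
#' `nChains x floor((nIter - burnIn) / thin)` predictive draws, and a cell's
#' own observed value never informs the model that predicts it.
#'
#' @param panel a [MetabolitePanel-class].
#' @param metabolite metabolite name.
#' @param folds a [makeFolds()] assignment for this metabolite.
#' @param prior a [priorSpec()].
#' @param cfg an [mcmcConfig()].
#' @return list with `table` (a [FlagTable-class] with draws populated and
#'   intervals still unset; pass to [flagCells()]) and `psrf` (folds x
#'   parameters matrix of Gelman-Rubin statistics, `NULL` for single-chain
#'   runs).
#' @export
posteriorPredictHeldout <- function(panel, metabolite = metaboliteNames(panel)[1],
                                    folds, prior = priorSpec(),
                                    cfg = mcmcConfig()) {
  stopifnot(inherits(folds, "FoldAssignment"))
  asg <- folds$assignment
  X <- covariates(panel)
  vals <- metaboliteValues(panel, metabolite)
  n_keep <- (cfg$nIter - cfg$burnIn) %/% cfg$thin
  n_draws <- n_keep * cfg$nChains
  draws <- matrix(NA_real_, nrow(asg), n_draws)
  psrf_all <- NULL
  for (f in seq_len(folds$nFolds)) {
    held <- asg[asg$fold == f, , drop = FALSE]
    if (nrow(held) == 0L) next
    fit <- tryCatch(
      fitBglm(panel, prior = prior, cfg = cfg, metabolite = metabolite,
              holdout = held),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e), call. = FALSE))
    if (cfg$nChains >= 2L) {
      rep_f <- psrfReport(fit)
      if (is.null(psrf_all))
        psrf_all <- matrix(NA_real_, folds$nFolds, length(rep_f@psrf),
                           dimnames = list(NULL, names(rep_f@psrf)))
      psrf_all[f, ] <- rep_f@psrf
    }
    b0 <- as.vector(fit@beta0)
    L <- length(fit@covariateNames)
    B1 <- if (L > 0L) apply(fit@beta1, 2, as.vector) else NULL
    sde <- sqrt(as.vector(fit@sigma2Eps))
    set.seed(cfg$seed + 7919L * f)
    for (r in seq_len(nrow(held))) {
      i <- held$individual[r]
      mu <- b0 + (if (L > 0L) as.numeric(B1 %*% X[i, ]) else 0) +
        as.vector(fit@s[, i, ])
      draws[which(asg$fold == f)[r], ] <- mu + stats::rnorm(n_draws, 0, sde)
    }
  }
  cells <- S4Vectors::DataFrame(
    individual = asg$individual, time = asg$time, metabolite = metabolite,
    observed = vals[cbind(asg$individual, asg$time)],
    hpdLower = NA_real_, hpdUpper = NA_real_,
    centralLower = NA_real_, centralUpper = NA_real_, flagged = FALSE)
  table <- methods::new("FlagTable", cells = cells, draws = draws, W = 95)
  list(table = table, psrf = psrf_all)
}

#' Compute prediction intervals and flags
#'
#' Fills the W\% HPD interval (the flagging boundary) and the equal-tailed
#' central interval (used for display, e.g. circos-style bar widths) of every
#' cell from its predictive draws, and flags cells whose observed value lies
#' outside the HPD interval. Cells without an observed value are never
#' flagged.
#'
#' @param table a [FlagTable-class] with draws populated.
#' @param W interval mass in percent (default 95).
#' @return the completed [FlagTable-class].
#' @export
flagCells <- function(table, W = 95) {
  stopifnot(methods::is(table, "FlagTable"))
  if (nrow(table@draws) != nrow(table@cells) || anyNA(table@draws))
    stop("predictive draws must be populated for all cells")
  cc <- table@cells
  n <- nrow(cc)
  hl <- hu <- cl <- cu <- numeric(n)
  fl <- logical(n)
  for (r in seq_len(n)) {
    h <- hpdInterval(table@draws[r, ], W)
    ce <- central_interval(table@draws[r, ], W)
    hl[r] <- h[1]; hu[r] <- h[2]; cl[r] <- ce[1]; cu[r] <- ce[2]
    fl[r] <- !is.na(cc$observed[r]) && (cc$observed[r] < h[1] || cc$observed[r] > h[2])
  }
  cc$hpdLower <- hl; cc$hpdUpper <- hu
  cc$centralLower <- cl; cc$centralUpper <- cu
  cc$flagged <- fl
  methods::initialize(table, cells = cc, W = W)
}

#' Full hold-out flagging pipeline for one metabolite
#'
#' Convenience wrapper: [makeFolds()], [posteriorPredictHeldout()] and
#' [flagCells()] in sequence.
#'
#' @inheritParams posteriorPredictHeldout
#' @param nFolds number of hold-out folds (default 25).
#' @param W HPD interval mass in percent (default 95).
#' @param foldSeed seed for the fold partition (defaults to `cfg$seed`).
#' @return list with `flags` (completed [FlagTable-class]), `psrf` (folds x
#'   parameters matrix) and `folds`.
#' @export
flagMetabolite <- function(panel, metabolite = metaboliteNames(panel)[1],
                           prior = priorSpec(), cfg = mcmcConfig(),
                           nFolds = 25L, W = 95, foldSeed = cfg$seed) {
  folds <- makeFolds(panel, metabolite, nFolds, foldSeed)
  pp <- posteriorPredictHeldout(panel, metabolite, folds, prior, cfg)
  list(flags = flagCells(pp$table, W), psrf = pp$psrf, folds = folds)
}

#' @rdname FlagTable-accessors
#' @export
setMethod("flaggedCells", "FlagTable", function(x)
  as.data.frame(x@cells[x@cells$flagged, , drop = FALSE]))

#' Accessors for FlagTable objects
#'
#' @param x a [FlagTable-class].
#' @return `flaggedCells` returns the flagged rows as a data.frame;
#'   `predictiveDraws` the cells x draws matrix.
#' @name FlagTable-accessors
NULL

#' @rdname FlagTable-accessors
#' @export
setMethod("predictiveDraws", "FlagTable", function(x) x@draws)

setMethod("show", "FlagTable", function(object) {
  cc <- object@cells
  cat("FlagTable:", nrow(cc), "cells,",
    length(unique(cc$metabolite)), "metabolite(s), W =", object@W, "%\n")
  if (!all(is.na(cc$hpdLower)))
    cat("  flagged cells:", sum(cc$flagged), "(",
        length(unique(cc$individual[cc$flagged])), "individuals )\n")
  else cat("  intervals not yet computed; run flagCells()\n")
})

#' Summarise flags across metabolites
#'
#' Produces the per-metabolite, per-time-point flag counts, the number of
#' unique flagged individuals per metabolite (an individual flagged at
#' several time points counts once), and the proportion of individuals
#' flagged in at least `k` metabolites.
#'
#' @param tables a [FlagTable-class] or list of them (one per metabolite,
#'   same individual roster).
#' @param k metabolite-count threshold for the cross-metabolite summary
#'   (default 3).
#' @return list with `cellCounts` (data.frame metabolite x time point),
#'   `uniqueCounts` (named integer vector per metabolite),
#'   `proportionAtLeastK` and `flaggedIndividuals` (ids flagged in >= k
#'   metabolites).
#' @export
summariseFlags <- function(tables, k = 3L) {
  if (methods::is(tables, "FlagTable")) tables <- list(tables)
  if (k < 1L) stop("k must be >= 1")
  cells <- do.call(rbind, lapply(tables, function(t) as.data.frame(t@cells)))
  roster <- sort(unique(cells$individual))
  mets <- unique(cells$metabolite)
  times <- sort(unique(cells$time))
  fl <- cells[cells$flagged, , drop = FALSE]
  cellCounts <- as.data.frame.matrix(table(
    factor(fl$metabolite, levels = mets), factor(fl$time, levels = times)))
  cellCounts <- cbind(metabolite = rownames(cellCounts), cellCounts)
  rownames(cellCounts) <- NULL
  uniqueCounts <- vapply(mets, function(m)
    length(unique(fl$individual[fl$metabolite == m])), integer(1))
  perInd <- vapply(roster, function(i)
    length(unique(fl$metabolite[fl$individual == i])), integer(1))
  list(cellCounts = cellCounts,
       uniqueCounts = uniqueCounts,
       proportionAtLeastK = mean(perInd >= k),
       flaggedIndividuals = roster[perInd >= k])
}
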