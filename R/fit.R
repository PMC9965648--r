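#' Prior specification for the random-intercept model
#'
#' Fixed-effect coefficients (intercept and covariate effects) receive
#' independent Gaussian priors centred at `betaMean` with variance
#' `betaVariance`; the two variance components (individual-effect variance
#' and residual variance) receive independent inverse-gamma priors with the
#' given shape and scale. The defaults are deliberately weak: an essentially
#' flat Gaussian (variance 1e10) and inverse-gamma(0.001, 0.001).
#'
#' @param betaMean,betaVariance Gaussian prior mean and variance for every
#'   fixed-effect coefficient.
#' @param varShape,varScale inverse-gamma shape and scale applied
#'   independently to both variance components.
#' @return a list of class `PriorSpec`.
#' @export
priorSpec <- function(betaMean = 0, betaVariance = 1e10,
                      varShape = 0.001, varScale = 0.001) {
  stopifnot(is.finite(betaMean), betaVariance > 0, varShape > 0, varScale > 0)
  structure(list(betaMean = betaMean, betaVariance = betaVariance,
                 varShape = varShape, varScale = varScale),
            class = "PriorSpec")
}

#' MCMC sampler configuration
#'
#' @param nChains number of independent chains (>= 2 recommended so the
#'   Gelman-Rubin diagnostic is available).
#' @param nIter total iterations per chain.
#' @param burnIn iterations discarded from the start of each chain.
#' @param thin keep every `thin`-th post-burn-in draw (default 2).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param overdispersedStarts start each chain from dispersed initial values
#'   (coefficients from N(0, 10 x var(y)), variances from the prior); needed
#'   for the between/within-chain convergence diagnostic to be meaningful.
#' @return a list of class `McmcConfig`. At least 100 retained draws per
#'   chain (`floor((nIter - burnIn) / thin)`) are required.
#' @export
mcmcConfig <- function(nChains = 4L, nIter = 5000L, burnIn = 2500L, thin = 2L,
                       seed = 1L, overdispersedStarts = TRUE) {
  nChains <- as.integer(nChains); nIter <- as.integer(nIter)
  burnIn <- as.integer(burnIn); thin <- as.integer(thin)
  stopifnot(nChains >= 1L, thin >= 1L, burnIn >= 0L, burnIn < nIter)
  retained <- (nIter - burnIn) %/% thin
  if (retained < 100L)
    stop("configuration retains only ", retained,
         " draws per chain; at least 100 are required")
  structure(list(nChains = nChains, nIter = nIter, burnIn = burnIn,
                 thin = thin, seed = as.integer(seed),
                 overdispersedStarts = isTRUE(overdispersedStarts)),
            class = "McmcConfig")
}

check_design <- function(W) {
  p <- ncol(W)
  cols <- colnames(W)
  sds <- apply(W[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0))
    stop("covariate column constant (confounded with the intercept): ",
         paste(cols[-1][sds == 0], collapse = ", "))
  qrW <- qr(W)
  if (qrW$rank < p) {
    dropped <- cols[qrW$pivot[(qrW$rank + 1):p]]
    stop("design matrix is singular; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit the Bayesian random-intercept model by blocked Gibbs sampling
#'
#' Models an observed metabolite level for individual i at time point t as
#' \deqn{y_{it} = \beta_0 + \sum_l \beta_{1,l} x_{il} + s_i + \epsilon_{it},}
#' with a per-individual random intercept \eqn{s_i \sim N(0, \sigma^2)} and
#' residual \eqn{\epsilon_{it} \sim N(0, \sigma_\epsilon^2)}. All full
#' conditionals are conjugate (Gaussian for the coefficients and the random
#' intercepts, inverse-gamma for the variances), so the posterior is sampled
#' by a blocked Gibbs sampler: no tuning, and the same stationary
#' distribution as a Metropolis-Hastings sampler for the same posterior.
#' Missing time points are simply absent from the likelihood, so unbalanced
#' panels are handled naturally.
#'
#' Draws are reproducible bit-for-bit given identical data, prior, and
#' configuration; internally individuals and cells are processed in a
#' canonical sorted order so the result is invariant to row permutations of
#' the input.
#'
#' @param y either a data.frame of observed triples with columns
#'   `individual`, `time`, `value`, or a [MetabolitePanel-class].
#' @param X numeric covariate matrix (individuals x L, rownames = ids;
#'   L = 0 gives an intercept-only model). Taken from the panel's covariates
#'   for the panel method.
#' @param prior a [priorSpec()].
#' @param cfg an [mcmcConfig()].
#' @param metabolite (panel method) metabolite to fit.
#' @param holdout (panel method) optional data.frame with columns
#'   `individual`, `time`: observed cells excluded from the likelihood.
#' @param ... passed through.
#' @return a [PosteriorSamples-class].
#' @examples
#' X <- matrix(rnorm(40), 40, 1, dimnames = list(paste0("i", 1:40), "age"))
#' y <- data.frame(individual = rep(rownames(X), each = 2),
#'                 time = rep(c("T1", "T2"), 40),
#'                 value = rnorm(80, 100 + 0.5 * rep(X[, 1], each = 2), 3))
#' fit <- fitBglm(y, X, cfg = mcmcConfig(nChains = 2, nIter = 600, burnIn = 300))
#' posteriorSummary(fit)
#' @rdname fitBglm
#' @export
setMethod("fitBglm", "data.frame", function(y, X, prior = priorSpec(),
                                            cfg = mcmcConfig(), ...) {
  stopifnot(all(c("individual", "time", "value") %in% colnames(y)))
  if (nrow(y) == 0L) stop("no observed cells to fit")
  if (!all(is.finite(y$value))) stop("observed values must be finite")
  if (missing(X) || is.null(X))
    X <- matrix(0, length(unique(y$individual)), 0,
                dimnames = list(sort(unique(as.character(y$individual))), NULL))
  ids_in <- rownames(X)
  if (is.null(ids_in)) stop("X must carry individual ids as rownames")
  if (!all(y$individual %in% ids_in))
    stop("individuals in y missing from X: ",
         paste(setdiff(y$individual, ids_in), collapse = ", "))
  if (cfg$nChains < 2L)
    warning("fewer than 2 chains: the Gelman-Rubin diagnostic will be unavailable")

  # canonical internal order: individuals sorted by id, cells by (id, time)
  ids <- sort(ids_in, method = "radix")
  Xs <- X[ids, , drop = FALSE]
  idx <- match(as.character(y$individual), ids)
  ord <- order(idx, as.character(y$time), method = "radix")
  yv <- y$value[ord]
  idx <- idx[ord]
  L <- ncol(Xs)
  W <- cbind(`(Intercept)` = 1, Xs)[idx, , drop = FALSE]  # one row per observation
  if (L > 0L) check_design(W)

  vy <- max(stats::var(yv), 1e-8)
  n_keep <- (cfg$nIter - cfg$burnIn) %/% cfg$thin
  N <- length(ids)
  beta0 <- matrix(NA_real_, n_keep, cfg$nChains)
  beta1 <- array(NA_real_, c(n_keep, L, cfg$nChains))
  s2s <- matrix(NA_real_, n_keep, cfg$nChains)
  s2e <- matrix(NA_real_, n_keep, cfg$nChains)
  s <- array(NA_real_, c(n_keep, N, cfg$nChains))
  for (ch in seq_len(cfg$nChains)) {
    set.seed(cfg$seed + ch - 1L)
    if (cfg$overdispersedStarts) {
      beta_init <- stats::rnorm(L + 1L, 0, sqrt(10 * vy))
      # prior draws, clamped to a numerically safe window around var(y)
      s2s0 <- min(max(1 / stats::rgamma(1, prior$varShape, rate = prior$varScale),
                      vy * 1e-4), vy * 1e4)
      s2e0 <- min(max(1 / stats::rgamma(1, prior$varShape, rate = prior$varScale),
                      vy * 1e-4), vy * 1e4)
    } else {
      beta_init <- c(mean(yv), rep(0, L))
      s2s0 <- s2e0 <- vy / 2
    }
    res <- gibbs_chain(yv, W, idx - 1L, N, prior$betaMean, prior$betaVariance,
                       prior$varShape, prior$varScale, cfg$nIter, cfg$burnIn,
                       cfg$thin, beta_init, s2s0, s2e0)
    beta0[, ch] <- res$beta[, 1]
    if (L > 0L) beta1[, , ch] <- res$beta[, -1, drop = FALSE]
    s2s[, ch] <- res$sigma2_s
    s2e[, ch] <- res$sigma2_eps
    s[, , ch] <- res$s
  }
  # report s in the caller's individual order
  back <- match(ids_in, ids)
  s <- s[, back, , drop = FALSE]
  dimnames(s)[[2]] <- ids_in
  dimnames(beta1)[[2]] <- colnames(Xs)
  methods::new("PosteriorSamples", beta0 = beta0, beta1 = beta1,
               sigma2S = s2s, sigma2Eps = s2e, s = s,
               individualIds = ids_in,
               covariateNames = if (L > 0L) colnames(Xs) else character(),
               config = unclass(cfg))
})

#' @rdname fitBglm
#' @export
setMethod("fitBglm", "MetabolitePanel", function(y, X, prior = priorSpec(),
                                                 cfg = mcmcConfig(),
                                                 metabolite = metaboliteNames(y)[1],
                                                 holdout = NULL, ...) {
  tr <- panelTriples(y, metabolite)
  if (!is.null(holdout) && nrow(holdout) > 0L) {
    drop <- paste(tr$individual, tr$time) %in% paste(holdout$individual, holdout$time)
    tr <- tr[!drop, , drop = FALSE]
  }
  fitBglm(tr, covariates(y), prior = prior, cfg = cfg)
})

#' Unnormalised log joint density of one parameter draw
#'
#' Gaussian log-likelihood of the observed triples given the linear
#' predictor (including the individual intercepts), plus the log prior
#' density of the intercepts, coefficients and variance components; constant
#' normalising terms are retained, so values are comparable across draws for
#' fixed data.
#'
#' @param params list with elements `beta0` (scalar), `beta1` (length-L),
#'   `s` (named by individual id), `sigma2S`, `sigma2Eps`.
#' @param y observed triples (`individual`, `time`, `value`).
#' @param X covariate matrix as in [fitBglm()].
#' @param prior a [priorSpec()].
#' @return finite numeric scalar.
#' @export
logJoint <- function(params, y, X, prior = priorSpec()) {
  if (params$sigma2S <= 0 || params$sigma2Eps <= 0)
    stop("variance parameters must be strictly positive")
  L <- if (is.null(X)) 0L else ncol(X)
  lp <- params$beta0 +
    (if (L > 0L) as.numeric(X[as.character(y$individual), , drop = FALSE] %*% params$beta1) else 0) +
    params$s[as.character(y$individual)]
  ll <- sum(stats::dnorm(y$value, lp, sqrt(params$sigma2Eps), log = TRUE))
  lps <- sum(stats::dnorm(params$s, 0, sqrt(params$sigma2S), log = TRUE))
  lpb <- sum(stats::dnorm(c(params$beta0, params$beta1), prior$betaMean,
                          sqrt(prior$betaVariance), log = TRUE))
  dinvgamma <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  lpv <- dinvgamma(params$sigma2S, prior$varShape, prior$varScale) +
    dinvgamma(params$sigma2Eps, prior$varShape, prior$varScale)
  out <- ll + lps + lpb + lpv
  if (!is.finite(out)) stop("log joint density is not finite")
  out
}

#' Posterior summaries of a fitted model
#'
#' Pools retained draws across chains and reports the posterior mean and an
#' equal-tailed credible interval for the intercept, each covariate
#' coefficient and the two variance components.
#'
#' @param fit a [PosteriorSamples-class].
#' @param prob credible-interval mass (default 0.95).
#' @return data.frame with columns `parameter`, `mean`, `lower`, `upper`.
#' @export
posteriorSummary <- function(fit, prob = 0.95) {
  draws <- parameterDraws(fit)
  al <- (1 - prob) / 2
  pooled <- lapply(draws, as.vector)
  data.frame(parameter = names(pooled),
             mean = vapply(pooled, mean, numeric(1)),
             lower = vapply(pooled, stats::quantile, numeric(1), probs = al),
             upper = vapply(pooled, stats::quantile, numeric(1), probs = 1 - al),
             row.names = NULL)
}

#' Per-chain draw matrices of the monitored scalar parameters
#'
#' @param fit a [PosteriorSamples-class].
#' @return named list of draws x chains matrices: `beta0`, one entry per
#'   covariate coefficient, `sigma2S` and `sigma2Eps`.
#' @export
parameterDraws <- function(fit) {
  out <- list(beta0 = fit@beta0)
  for (l in seq_along(fit@covariateNames))
    out[[paste0("beta1.", fit@covariateNames[l])]] <-
      fit@beta1[, l, , drop = TRUE]
  out$sigma2S <- fit@sigma2S
  out$sigma2Eps <- fit@sigma2Eps
  lapply(out, function(m) if (is.matrix(m)) m else matrix(m, ncol = ncol(fit@beta0)))
}

setMethod("show", "PosteriorSamples", function(object) {
  cat("PosteriorSamples:", ncol(object@beta0), "chains x",
      nrow(object@beta0), "retained draws;",
      length(object@individualIds), "individual intercepts\n")
  ps <- posteriorSummary(object)
  print(ps, digits = 4)
})
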