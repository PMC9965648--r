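#' Gelman-Rubin potential scale reduction factor
#'
#' The classic univariate PSRF comparing between- and within-chain
#' variances:
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \; W_v + B_v / n}{W_v}},}
#' where \eqn{W_v} is the mean within-chain sample variance and
#' \eqn{B_v = n \cdot \mathrm{var}(\bar\theta_c)} the between-chain variance
#' of the chain means (sample variances with the n-1 denominator). Values
#' near 1 indicate that the chains have mixed; 0.9-1.05 is the conventional
#' acceptance window. No split-chain or degrees-of-freedom correction is
#' applied.
#'
#' @param chains numeric matrix (draws x chains) or list of equal-length
#'   numeric vectors, one per chain, for a single scalar parameter.
#' @return the PSRF, a finite numeric scalar.
#' @examples
#' psrf(cbind(rnorm(1000), rnorm(1000)))
#' @export
psrf <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L)
      stop("all chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  stopifnot(is.matrix(chains))
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2L) stop("at least 2 chains are required")
  if (n < 2L) stop("at least 2 draws per chain are required")
  Wv <- mean(apply(chains, 2, stats::var))
  if (Wv == 0) stop("zero within-chain variance: PSRF is undefined")
  Bv <- n * stats::var(colMeans(chains))
  sqrt(((n - 1) / n * Wv + Bv / n) / Wv)
}

#' Convergence report for a fitted model
#'
#' Computes the PSRF for every monitored scalar parameter of a
#' [fitBglm()] fit (intercept, covariate coefficients, both variance
#' components) on the retained, thinned draws, and checks all values
#' against the 0.9-1.05 window.
#'
#' @param fit a [PosteriorSamples-class] with at least 2 chains.
#' @return a [PsrfReport-class].
#' @export
psrfReport <- function(fit) {
  draws <- parameterDraws(fit)
  vals <- vapply(draws, psrf, numeric(1))
  methods::new("PsrfReport", psrf = vals, mean = mean(vals),
               sd = stats::sd(vals),
               pass = all(vals >= 0.9 & vals <= 1.05))
}

setMethod("show", "PsrfReport", function(object) {
  cat("PsrfReport: mean", format(object@mean, digits = 5),
      "( sd", format(object@sd, digits = 3), ")",
      if (object@pass) "- converged (all in [0.9, 1.05])\n" else "- NOT converged\n")
  print(round(object@psrf, 4))
})

#' Sample autocorrelation of an MCMC chain
#'
#' Autocorrelation at lags 0..`maxLag`, as used to choose the thinning
#' interval; the lag-0 value is exactly 1.
#'
#' @param chain numeric vector of draws.
#' @param maxLag largest lag, < length(chain).
#' @return numeric vector of length `maxLag + 1`, names `lag0`...
#' @export
chainAutocorrelation <- function(chain, maxLag = 20L) {
  stopifnot(length(chain) > maxLag)
  if (stats::sd(chain) == 0) stop("constant chain: autocorrelation is undefined")
  ac <- stats::acf(chain, lag.max = maxLag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  names(ac) <- paste0("lag", 0:maxLag)
  ac
}
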