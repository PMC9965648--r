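test_that("intercept-only fit on constant data recovers the constant", {
  y <- data.frame(individual = rep(sprintf("i%d", 1:10), each = 3),
                  time = rep(paste0("T", 1:3), 10),
                  value = 42)
  fit <- suppressWarnings(fitBglm(y, NULL, cfg = quick_cfg()))
  b0 <- mean(fit@beta0)
  expect_lt(abs(b0 - 42), 0.5)
  expect_true(all(fit@sigma2S > 0), all(fit@sigma2Eps > 0))
})

test_that("draws are bit-reproducible and invariant to row permutation", {
  p <- toy_panel(N = 10, seed = 3)
  tr <- panelTriples(p)
  X <- covariates(p)
  cfg <- quick_cfg(seed = 9)
  f1 <- fitBglm(tr, X, cfg = cfg)
  f2 <- fitBglm(tr, X, cfg = cfg)
  expect_identical(f1@beta0, f2@beta0)
  expect_identical(f1@s, f2@s)

  # permute both the triples and the covariate rows
  set.seed(1)
  perm <- sample(nrow(X))
  f3 <- fitBglm(tr[sample(nrow(tr)), ], X[perm, , drop = FALSE], cfg = cfg)
  expect_identical(f1@beta0, f3@beta0)
  expect_identical(f1@beta1, f3@beta1)
  ids <- individualIds(p)
  expect_identical(f1@s[, ids, ], f3@s[, ids, ])
})

test_that("degenerate designs raise errors naming the offending column", {
  p <- toy_panel(N = 8)
  tr <- panelTriples(p)
  X <- covariates(p)
  Xc <- cbind(X, height = 170)
  expect_error(fitBglm(tr, Xc, cfg = quick_cfg()), "height")
  Xd <- cbind(X, age2 = 2 * X[, "age"])
  expect_error(fitBglm(tr, Xd, cfg = quick_cfg()), "age2")
  expect_warning(
    fitBglm(tr, X, cfg = mcmcConfig(nChains = 1, nIter = 500, burnIn = 100,
                                    seed = 1)),
    "Gelman-Rubin")
})

test_that("the sampler matches the closed-form Gaussian posterior when the
           variances are pinned", {
  # inverse-gamma(a, a*v) with huge a pins a variance draw at v; with both
  # components pinned at 1 and s integrated out, the beta posterior is the
  # conjugate Gaussian N(A^-1 X'Vinv y, A^-1) with V = I + Z Z' and
  # A = X'Vinv X + I/tau -- an independent closed-form oracle
  set.seed(21)
  N <- 15; Tn <- 3
  ids <- sprintf("i%02d", 1:N)
  X <- matrix(rnorm(N), N, 1, dimnames = list(ids, "x"))
  s <- rnorm(N, 0, 1)
  tr <- data.frame(individual = rep(ids, each = Tn),
                   time = rep(paste0("T", 1:Tn), N),
                   value = 10 + 2 * rep(X[, 1], each = Tn) + rep(s, each = Tn) +
                     rnorm(N * Tn, 0, 1))
  a <- 1e7
  prior <- priorSpec(betaVariance = 1e6, varShape = a, varScale = a)
  fit <- fitBglm(tr, X, prior = prior,
                 cfg = mcmcConfig(nChains = 2, nIter = 3000, burnIn = 500,
                                  thin = 1, seed = 5))
  Z <- outer(rep(ids, each = Tn), ids, "==") * 1
  V <- diag(N * Tn) + Z %*% t(Z)
  Wd <- cbind(1, rep(X[, 1], each = Tn))
  Vinv <- solve(V)
  A <- t(Wd) %*% Vinv %*% Wd + diag(2) / 1e6
  m <- solve(A, t(Wd) %*% Vinv %*% tr$value)
  Sg <- solve(A)
  got <- c(mean(fit@beta0), mean(fit@beta1))
  # posterior-sd-scaled tolerance with a conservative effective sample size
  expect_lt(abs(got[1] - m[1]), 6 * sqrt(Sg[1, 1]) / sqrt(50))
  expect_lt(abs(got[2] - m[2]), 6 * sqrt(Sg[2, 2]) / sqrt(50))
  # the pinned variances actually held
  expect_lt(abs(mean(fit@sigma2S) - 1), 0.01)
  expect_lt(abs(mean(fit@sigma2Eps) - 1), 0.01)
})

test_that("a tight prior on the coefficients shrinks them toward zero", {
  p <- toy_panel(N = 20, seed = 8)
  tr <- panelTriples(p)
  X <- covariates(p)
  wide <- fitBglm(tr, X, priorSpec(betaVariance = 1e10), quick_cfg())
  tight <- fitBglm(tr, X, priorSpec(betaVariance = 1e-6), quick_cfg())
  expect_gt(abs(mean(wide@beta1)), 10 * abs(mean(tight@beta1)))
  expect_lt(abs(mean(tight@beta1)), 1e-2)
})

test_that("log joint density behaves like a Gaussian likelihood plus priors", {
  y <- data.frame(individual = c("a", "a", "b"), time = c("T1", "T2", "T1"),
                  value = c(1.2, 0.8, 2.5))
  X <- matrix(c(0.5, -1), 2, 1, dimnames = list(c("a", "b"), "x"))
  par <- list(beta0 = 1, beta1 = 0.3, s = c(a = 0.1, b = -0.2),
              sigma2S = 0.5, sigma2Eps = 0.8)
  # hand-summed oracle: term-by-term densities
  mu <- par$beta0 + X[y$individual, 1] * par$beta1 + par$s[y$individual]
  byhand <- sum(dnorm(y$value, mu, sqrt(0.8), log = TRUE)) +
    sum(dnorm(par$s, 0, sqrt(0.5), log = TRUE)) +
    sum(dnorm(c(1, 0.3), 0, sqrt(1e10), log = TRUE)) +
    (0.001 * log(0.001) - lgamma(0.001) - 1.001 * log(0.5) - 0.001 / 0.5) +
    (0.001 * log(0.001) - lgamma(0.001) - 1.001 * log(0.8) - 0.001 / 0.8)
  expect_equal(logJoint(par, y, X), byhand, tolerance = 1e-12)

  # doubling the residual variance with zero residuals decreases the density
  y0 <- y; y0$value <- mu
  par2 <- par; par2$sigma2Eps <- 2 * par$sigma2Eps
  expect_gt(logJoint(par, y0, X), logJoint(par2, y0, X))

  # translation invariance of the likelihood term
  shift <- 5
  ys <- y; ys$value <- y$value + shift
  pars <- par; pars$beta0 <- par$beta0 + shift
  prior_flat <- priorSpec(betaVariance = 1e30)
  expect_equal(logJoint(pars, ys, X, prior_flat),
               logJoint(par, y, X, prior_flat), tolerance = 1e-9)

  par_bad <- par; par_bad$sigma2Eps <- -1
  expect_error(logJoint(par_bad, y, X), "positive")
})

test_that("posterior draws respect the support and chain-shape contracts", {
  p <- toy_panel(N = 10)
  fit <- fitBglm(p, cfg = quick_cfg(nChains = 3))
  expect_identical(ncol(fit@beta0), 3L)
  expect_identical(nrow(fit@beta0), (700L - 300L) %/% 2L)
  expect_true(all(fit@sigma2S > 0))
  expect_true(all(fit@sigma2Eps > 0))
  expect_identical(dim(fit@s)[2], 10L)
  sm <- posteriorSummary(fit)
  expect_true(all(c("beta0", "beta1.age", "sigma2S", "sigma2Eps") %in%
                    sm$parameter))
  expect_true(all(sm$lower <= sm$mean & sm$mean <= sm$upper))
})
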