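# Fixtures are built in code; nothing is read from disk.

# small hand-made panel: N individuals x T time points, one metabolite,
# linear age effect plus individual shifts, optional missing cells
toy_panel <- function(N = 12, T = 4, seed = 42, metabolite = "Ala",
                      missing = NULL, sd_ind = 5, sd_eps = 2) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(N))
  age <- round(runif(N, 20, 60))
  y <- 100 + 0.5 * age + rnorm(N, 0, sd_ind) +
    matrix(rnorm(N * T, 0, sd_eps), N, T)
  dimnames(y) <- list(ids, paste0("T", seq_len(T)))
  if (!is.null(missing)) y[missing] <- NA
  MetabolitePanel(stats::setNames(list(y), metabolite),
                  covariates = data.frame(age = age))
}

# fast MCMC settings for unit tests (kept above the 100-draw floor)
quick_cfg <- function(seed = 1, nChains = 2) {
  mcmcConfig(nChains = nChains, nIter = 700, burnIn = 300, thin = 2,
             seed = seed)
}

# brute-force shortest-window HPD: examine every window explicitly
bf_hpd <- function(draws, W) {
  sorted <- sort(draws)
  n <- length(sorted)
  k <- ceiling(W / 100 * n)
  best <- c(-Inf, Inf)
  for (j in seq_len(n - k + 1)) {
    if (sorted[j + k - 1] - sorted[j] < best[2] - best[1])
      best <- c(sorted[j], sorted[j + k - 1])
  }
  best
}

# wide CSV fixture written to a temp file, built from a toy panel
toy_wide_csv <- function(N = 20, seed = 7, path = tempfile(fileext = ".csv")) {
  set.seed(seed)
  ids <- sprintf("id%03d", seq_len(N))
  df <- data.frame(id = ids,
                   age = round(rnorm(N, 35, 12), 1),
                   sex = sample(c("F", "M"), N, replace = TRUE),
                   BMI = round(rnorm(N, 24, 3), 1))
  for (tl in paste0("T", 1:4))
    df[[paste0("Ala_", tl)]] <- round(rnorm(N, 350, 40), 3)
  write.csv(df, path, row.names = FALSE)
  path
}
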