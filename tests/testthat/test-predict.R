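test_that("hpdInterval finds the leftmost shortest window", {
  expect_equal(unname(hpdInterval(1:100, 95)), c(1, 95))
  # closed-form Gaussian oracle
  set.seed(1)
  z <- rnorm(1e5)
  h <- hpdInterval(z, 95)
  expect_lt(abs(h["lower"] + 1.96), 0.05)
  expect_lt(abs(h["upper"] - 1.96), 0.05)
  # brute-force oracle on assorted shapes, and HPD beats the central interval
  set.seed(2)
  for (draws in list(rexp(500), rgamma(400, 2), rnorm(300), rlnorm(250))) {
    for (W in c(80, 90, 95, 99)) {
      expect_identical(unname(hpdInterval(draws, W)), bf_hpd(draws, W))
    }
    h <- hpdInterval(draws, 95)
    ce <- quantile(draws, c(0.025, 0.975), names = FALSE)
    expect_lte(h["upper"] - h["lower"], ce[2] - ce[1])
  }
  expect_error(hpdInterval(c(1, 2), 10), "too few draws")
})

test_that("HPD intervals are nested in W and so are the flags", {
  set.seed(3)
  draws <- rgamma(2000, 3)
  h90 <- hpdInterval(draws, 90)
  h99 <- hpdInterval(draws, 99)
  expect_lte(h99["lower"], h90["lower"])
  expect_gte(h99["upper"], h90["upper"])

  p <- toy_panel(N = 8, seed = 5)
  res <- flagMetabolite(p, cfg = quick_cfg(), nFolds = 4)
  f90 <- flagCells(methods::initialize(res$flags), W = 90)
  f99 <- flagCells(methods::initialize(res$flags), W = 99)
  flagged90 <- paste(f90@cells$individual, f90@cells$time)[f90@cells$flagged]
  flagged99 <- paste(f99@cells$individual, f99@cells$time)[f99@cells$flagged]
  expect_true(all(flagged99 %in% flagged90))
})

test_that("folds partition the observed cells evenly with stratification", {
  p <- toy_panel(N = 150, T = 4, seed = 10)
  fa <- makeFolds(p, nFolds = 25, seed = 4)
  asg <- fa$assignment
  # 600 cells over 25 folds: exactly 24 each
  expect_identical(as.integer(table(asg$fold)), rep(24L, 25))
  # each individual's 4 cells in 4 distinct folds
  byInd <- split(asg$fold, asg$individual)
  expect_true(all(vapply(byInd, function(f) length(unique(f)) == length(f),
                         logical(1))))
  # brute-force set check: union = all observed cells, no overlap
  key <- paste(asg$individual, asg$time)
  tr <- panelTriples(p)
  expect_setequal(key, paste(tr$individual, tr$time))
  expect_identical(anyDuplicated(key), 0L)
  # deterministic given seed
  fb <- makeFolds(p, nFolds = 25, seed = 4)
  expect_identical(fa, fb)
})

test_that("folds stay balanced under missingness and reject impossible strata", {
  p <- toy_panel(N = 21, T = 4, seed = 11,
                 missing = cbind(c(1, 1, 2, 5), c(1, 2, 4, 3)))
  fa <- makeFolds(p, nFolds = 5, seed = 2)
  sizes <- table(factor(fa$assignment$fold, levels = 1:5))
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(makeFolds(p, nFolds = 3, seed = 1), "more observed cells")
})

test_that("held-out predictive draws honour the counting contract and
           degenerate variances collapse to the intercept", {
  p <- toy_panel(N = 8, seed = 6)
  cfg <- quick_cfg()
  fa <- makeFolds(p, nFolds = 4, seed = 1)
  pp <- posteriorPredictHeldout(p, folds = fa, cfg = cfg)
  expect_identical(ncol(pp$table@draws),
                   cfg$nChains * ((cfg$nIter - cfg$burnIn) %/% cfg$thin))
  expect_false(anyNA(pp$table@draws))

  # variances pinned near zero and a flat response: draws concentrate at b0
  y <- matrix(50 + rnorm(32, 0, 1e-4), 8, 4,
              dimnames = list(sprintf("i%d", 1:8), paste0("T", 1:4)))
  p0 <- MetabolitePanel(list(m = y))
  pin <- priorSpec(varShape = 1e6, varScale = 1e6 * 1e-8)
  pp0 <- posteriorPredictHeldout(p0, folds = makeFolds(p0, nFolds = 4, seed = 1),
                                 prior = pin, cfg = cfg)
  expect_lt(max(abs(pp0$table@draws - 50)), 0.05)
})

test_that("flags agree with a brute-force recomputation from the draws", {
  p <- toy_panel(N = 10, seed = 12)
  res <- flagMetabolite(p, cfg = quick_cfg(), nFolds = 5)
  cc <- res$flags@cells
  for (r in seq_len(nrow(cc))) {
    h <- bf_hpd(res$flags@draws[r, ], 95)
    expect_identical(cc$flagged[r], cc$observed[r] < h[1] | cc$observed[r] > h[2])
  }
  # interior point is never flagged, far exterior always is
  tb <- res$flags
  cc2 <- tb@cells
  cc2$observed[1] <- median(tb@draws[1, ])
  cc2$observed[2] <- max(tb@draws[2, ]) + 10 * sd(tb@draws[2, ])
  cc2$observed[3] <- NA
  # reset to the pre-interval state before recomputing the flags
  cc2$hpdLower <- cc2$hpdUpper <- NA_real_
  cc2$flagged <- FALSE
  tb2 <- flagCells(methods::initialize(tb, cells = cc2), W = 95)
  expect_false(tb2@cells$flagged[1])
  expect_true(tb2@cells$flagged[2])
  expect_false(tb2@cells$flagged[3])  # missing observation: never flagged
})

test_that("a held-out cell's value cannot influence its own prediction", {
  p1 <- toy_panel(N = 8, seed = 13)
  v <- metaboliteValues(p1)
  v[3, 2] <- v[3, 2] + 500  # corrupt one cell
  p2 <- MetabolitePanel(list(Ala = v), covariates = as.data.frame(covariates(p1)))
  cfg <- quick_cfg(seed = 2)
  fa1 <- makeFolds(p1, nFolds = 4, seed = 7)
  fa2 <- makeFolds(p2, nFolds = 4, seed = 7)
  expect_identical(fa1$assignment, fa2$assignment)
  d1 <- posteriorPredictHeldout(p1, folds = fa1, cfg = cfg)$table
  d2 <- posteriorPredictHeldout(p2, folds = fa2, cfg = cfg)$table
  r <- which(d1@cells$individual == individualIds(p1)[3] & d1@cells$time == "T2")
  expect_identical(d1@draws[r, ], d2@draws[r, ])
})

test_that("summariseFlags counts individuals once and matches a manual tally", {
  cells <- S4Vectors::DataFrame(
    individual = rep(sprintf("i%d", 1:5), each = 4),
    time = rep(paste0("T", 1:4), 5),
    metabolite = "A",
    observed = 1, hpdLower = 0, hpdUpper = 2,
    centralLower = 0, centralUpper = 2,
    flagged = FALSE)
  # individual i1 flagged at 3 time points of metabolite A: unique count 1
  cells$flagged[1:3] <- TRUE
  cells$observed[1:3] <- 5
  tabA <- methods::new("FlagTable", cells = cells,
                       draws = matrix(numeric(), 0, 0), W = 95)
  cellsB <- cells
  cellsB$metabolite <- "B"
  cellsB$observed <- 1
  cellsB$flagged <- c(rep(FALSE, 4), TRUE, rep(FALSE, 15))
  cellsB$observed[5] <- 5
  tabB <- methods::new("FlagTable", cells = cellsB,
                       draws = matrix(numeric(), 0, 0), W = 95)
  sm <- summariseFlags(list(tabA, tabB), k = 1)
  expect_identical(sm$uniqueCounts, c(A = 1L, B = 1L))
  expect_identical(sum(sm$cellCounts[sm$cellCounts$metabolite == "A", -1]), 3L)
  # i1 flagged in A only, i2 in B only: proportion with >= 2 metabolites is 0
  expect_identical(summariseFlags(list(tabA, tabB), k = 2)$proportionAtLeastK, 0)
  expect_identical(sm$proportionAtLeastK, 2 / 5)
  # manual exhaustive tally of the flag matrix
  allc <- rbind(as.data.frame(cells), as.data.frame(cellsB))
  for (m in c("A", "B")) for (tl in paste0("T", 1:4)) {
    expect_identical(
      sm$cellCounts[sm$cellCounts$metabolite == m, tl],
      sum(allc$flagged[allc$metabolite == m & allc$time == tl]))
  }
  # no flags anywhere
  cells0 <- cells; cells0$flagged <- FALSE; cells0$observed <- 1
  tab0 <- methods::new("FlagTable", cells = cells0,
                       draws = matrix(numeric(), 0, 0), W = 95)
  sm0 <- summariseFlags(tab0, k = 3)
  expect_identical(sum(as.matrix(sm0$cellCounts[, -1])), 0L)
  expect_identical(sm0$proportionAtLeastK, 0)
  expect_error(summariseFlags(tab0, k = 0), "k must be")
})
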