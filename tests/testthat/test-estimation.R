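test_that("sufficient counts match a brute-force row scan", {
  net <- buildWrkyNetwork()
  toy <- binFixture(matrix(
    c(1, 1, 0, 0,   # A
      rep(0L, 4), rep(0L, 4), rep(0L, 4), rep(0L, 4),
      rep(0L, 4), rep(0L, 4), rep(0L, 4)),
    ncol = 8, dimnames = list(NULL, LETTERS[1:8])))
  counts <- countSufficientStats(toy, net)
  a <- counts[counts$node == "A", ]
  expect_equal(a$n, 4)
  expect_equal(a$k, 2)
  # per node, n sums to the observation count
  expect_true(all(tapply(counts$n, counts$node, sum) == 4))

  # a parent configuration that never occurs has n = 0: here A=0,B=1 for C
  cAB <- counts[counts$node == "C" & counts$config == "01", ]
  expect_equal(cAB$n, 0)

  # independent row-scan oracle on random complete datasets
  withr::with_seed(51, {
    for (rep in 1:3) {
      d <- forwardSample(net, randomParameters(net), 200, seed = rep)
      counts <- countSufficientStats(d, net)
      v <- binValues(d)
      for (i in seq_len(nrow(counts))) {
        pa <- parentSets(net, counts$node[i])
        want <- as.integer(strsplit(counts$config[i], "")[[1]])
        hit <- rep(TRUE, nrow(v))
        for (j in seq_along(pa)) hit <- hit & v[, pa[j]] == want[j]
        expect_equal(counts$n[i], sum(hit))
        expect_equal(counts$k[i], sum(v[hit, counts$node[i]]))
      }
    }
  })

  miss <- binFixture(matrix(NA_integer_, 2, 8,
                            dimnames = list(NULL, LETTERS[1:8])), "missing")
  expect_error(countSufficientStats(miss, net), "synthesize")
})

test_that("Beta-Binomial updating follows the conjugate closed form", {
  net <- makeNetwork(list(A = character(0)))
  d <- binFixture(matrix(c(rep(1L, 7), rep(0L, 3)), ncol = 1,
                         dimnames = list(NULL, "A")))
  ps <- bayesianEstimate(countSufficientStats(d, net))
  tab <- paramTable(ps)
  expect_equal(tab$alpha, 8)
  expect_equal(tab$beta, 4)
  expect_equal(tab$theta, 8 / 12)

  # no data: pure prior mean
  net2 <- makeNetwork(list(A = character(0), B = "A"))
  d2 <- binFixture(matrix(c(1L, 1L), ncol = 2, dimnames = list(NULL, c("A", "B"))))
  ps2 <- bayesianEstimate(countSufficientStats(d2, net2))
  expect_equal(getTheta(ps2, "B", 0), 0.5)

  # never reaches the boundary: all-zero column stays strictly positive
  d3 <- binFixture(matrix(c(rep(1L, 1000), rep(0L, 1000)), ncol = 2,
                          dimnames = list(NULL, c("A", "B"))))
  ps3 <- bayesianEstimate(countSufficientStats(d3, net2))
  expect_equal(getTheta(ps3, "B", 1), 1 / 1002)
  expect_gt(getTheta(ps3, "B", 1), 0)

  expect_error(bayesianEstimate(countSufficientStats(d3, net2),
                                prior = c(0, 1)), "positive")
  # per-entry priors override the default
  pr <- data.frame(node = c("A", "B", "B"), config = c("", "0", "1"),
                   alpha = c(5, 1, 1), beta = c(5, 1, 1))
  ps4 <- bayesianEstimate(countSufficientStats(d2, net2), prior = pr)
  expect_equal(getTheta(ps4, "A"), 6 / 11)
})

test_that("MLE is the count ratio and flags unobserved configurations", {
  net <- makeNetwork(list(A = character(0), B = "A"))
  d <- binFixture(matrix(c(rep(1L, 10), rep(1L, 7), rep(0L, 3)), ncol = 2,
                         dimnames = list(NULL, c("A", "B"))))
  ps <- suppressMessages(mleEstimate(countSufficientStats(d, net)))
  expect_equal(getTheta(ps, "B", 1), 0.7)
  # boundary is reachable under MLE (contrast with the Bayesian estimate)
  expect_equal(getTheta(ps, "A"), 1.0)
  # A=0 never occurs: undefined, reported, and refused downstream
  tab <- paramTable(ps)
  expect_true(tab$undefined[tab$node == "B" & tab$config == "0"])
  expect_error(getTheta(ps, "B", 0), "undefined")
  expect_message(mleEstimate(countSufficientStats(d, net)), "undefined")

  bayes <- bayesianEstimate(countSufficientStats(d, net))
  filled <- suppressMessages(fillUndefined(ps, bayes))
  expect_equal(getTheta(filled, "B", 0), 0.5)
})

test_that("both estimators recover generating parameters and converge", {
  net <- buildWrkyNetwork()
  withr::with_seed(61, truth <- randomParameters(net, margin = 0.2))
  d <- forwardSample(net, truth, 20000, seed = 62)
  counts <- countSufficientStats(d, net)
  bayes <- bayesianEstimate(counts)
  mle <- mleEstimate(counts)
  tt <- paramTable(truth)
  for (ps in list(bayes, mle)) {
    tab <- paramTable(ps)
    for (i in seq_len(nrow(tab))) {
      if (tab$n[i] == 0) next
      th <- tt$theta[tt$node == tab$node[i] & tt$config == tab$config[i]]
      tol <- 3 * sqrt(th * (1 - th) / tab$n[i])
      expect_lt(abs(tab$theta[i] - th), tol)
    }
  }
  cmp <- compareEstimates(bayes, mle)
  expect_lt(attr(cmp, "maxDifference"), 0.01)

  # identical inputs compare to zero everywhere
  same <- compareEstimates(bayes, bayes)
  expect_true(all(same$difference == 0))
  expect_equal(attr(same, "maxDifference"), 0)

  # at n = 2 the two estimators can disagree by up to 0.25: k = 0 gives
  # MLE 0 and posterior mean 1/4
  tiny <- makeNetwork(list(A = character(0)))
  d0 <- binFixture(matrix(c(0L, 0L), ncol = 1, dimnames = list(NULL, "A")))
  c0 <- countSufficientStats(d0, tiny)
  expect_equal(abs(getTheta(bayesianEstimate(c0), "A") -
                     paramTable(mleEstimate(c0))$theta), 0.25)

  # row order never changes an estimate
  shuffled <- binFixture(binValues(d)[sample(nObs(d)), ])
  expect_equal(paramTable(bayesianEstimate(countSufficientStats(shuffled, net))),
               paramTable(bayes))

  expect_error(compareEstimates(bayes, bayesianEstimate(
    countSufficientStats(d0, tiny))), "different structures")
})

test_that("comparison table uses conditional-probability labels", {
  net <- buildWrkyNetwork()
  d <- forwardSample(net, uniformParameters(net), 50, seed = 1)
  counts <- countSufficientStats(d, net)
  cmp <- compareEstimates(bayesianEstimate(counts),
                          suppressMessages(mleEstimate(counts)))
  expect_true("P(A1)" %in% cmp$probability)
  expect_true("P(C1 |A1,B1)" %in% cmp$probability)
  expect_true("P(D1 |A1)" %in% cmp$probability)
  expect_equal(nrow(cmp), 22)
})
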