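test_that("WRKY network has the fixed pathway structure", {
  net <- buildWrkyNetwork()
  expect_setequal(nodeIds(net), LETTERS[1:8])
  expect_equal(sum(isComplexNode(net)), 4)
  expect_setequal(names(which(isComplexNode(net))), c("C", "D", "E", "G"))
  expect_equal(parentSets(net, "A"), character(0))
  expect_equal(parentSets(net, "B"), character(0))
  expect_setequal(parentSets(net, "C"), c("A", "B"))
  expect_equal(parentSets(net, "D"), "A")
  expect_equal(parentSets(net, "E"), "B")
  expect_equal(parentSets(net, "F"), "C")
  expect_equal(parentSets(net, "G"), "F")
  expect_setequal(parentSets(net, "H"), c("D", "E", "G"))
  # 22 local probabilities in total: 1+1+4+2+2+2+2+8
  expect_equal(sum(2^lengths(parentSets(net))), 22)
  # labels are metadata and overridable; structure identical
  net2 <- buildWrkyNetwork(labels = c(C = "WRKY18-18", D = "WRKY18-40"))
  expect_equal(unname(nodeLabels(net2)["C"]), "WRKY18-18")
  expect_equal(parentSets(net2), parentSets(net))
  expect_error(buildWrkyNetwork(labels = c(Z = "nope")), "unknown node")
})

test_that("structural validation reports cycles, isolation and unreachability", {
  expect_silent(validateStructure(buildWrkyNetwork()))
  rep <- validateStructure(buildWrkyNetwork())
  expect_true(rep$acyclic)
  expect_true(rep$connected)
  expect_length(rep$unreachable, 0)
  expect_equal(rep$topologicalOrder[1:2], c("A", "B"))

  expect_error(makeNetwork(list(A = "B", B = "A")), "cycle.*A, B")

  withZ <- makeNetwork(c(parentSets(buildWrkyNetwork()),
                         list(Z = character(0))))
  warns <- testthat::capture_warnings(
    rep2 <- validateStructure(withZ, target = "H"))
  expect_true(any(grepl("Z", warns)))
  expect_equal(rep2$isolated, "Z")
  expect_equal(rep2$unreachable, "Z")
})

test_that("joint probability factorizes and normalizes", {
  net <- buildWrkyNetwork()
  unif <- uniformParameters(net)
  full <- setNames(rep(1L, 8), LETTERS[1:8])
  expect_equal(jointProbability(net, unif, full), 1 / 256)

  zeroA <- uniformParameters(net)
  zeroA@table$theta[zeroA@table$node == "A"] <- 0
  expect_equal(jointProbability(net, zeroA, full), 0)

  expect_error(jointProbability(net, unif, c(A = 1)), "missing")

  withr::with_seed(11, {
    for (i in 1:5) {
      ps <- randomParameters(net)
      jv <- oracleJointVector(net, ps)
      total <- sum(vapply(seq_len(nrow(jv$assignments)), function(r)
        jointProbability(net, ps, jv$assignments[r, ]), numeric(1)))
      expect_equal(total, 1, tolerance = 1e-12)
    }
  })
})

test_that("marginals agree with brute-force enumeration", {
  net <- buildWrkyNetwork()
  unif <- uniformParameters(net)
  expect_equal(marginalProbability(net, unif, c(A = 1)), 0.5)

  # full-assignment query with no evidence reduces to the joint
  full <- setNames(c(1, 0, 1, 1, 0, 1, 0, 1), LETTERS[1:8])
  withr::with_seed(12, ps <- randomParameters(net))
  expect_equal(marginalProbability(net, ps, full),
               jointProbability(net, ps, full))

  # three-node example: independent roots, P(A=1, B=0) = 0.7 * 0.8
  ex <- exampleDecisionNetwork()
  expect_equal(marginalProbability(ex$network, ex$parameters,
                                   c(A = 1, B = 0)), 0.56)

  # random query/evidence pairs against the oracle
  withr::with_seed(13, {
    for (i in 1:10) {
      ps <- randomParameters(net)
      picks <- sample(LETTERS[1:8], 4)
      q <- setNames(sample(0:1, 2, replace = TRUE), picks[1:2])
      e <- setNames(sample(0:1, 2, replace = TRUE), picks[3:4])
      expect_equal(marginalProbability(net, ps, q, e),
                   oracleMarginal(net, ps, as.list(q), as.list(e)),
                   tolerance = 1e-12)
    }
  })

  expect_error(marginalProbability(net, unif, c(A = 1), c(A = 0)), "disjoint")
  zeroA <- uniformParameters(net)
  zeroA@table$theta[zeroA@table$node == "A"] <- 0
  expect_error(marginalProbability(net, zeroA, c(B = 1), c(A = 1)),
               "zero probability")
})

test_that("forward sampling is reproducible and matches the generator", {
  net <- buildWrkyNetwork()
  sureA <- uniformParameters(net)
  sureA@table$theta[sureA@table$node == "A"] <- 1
  d <- forwardSample(net, sureA, 200, seed = 5)
  expect_true(all(binValues(d)[, "A"] == 1L))

  d1 <- forwardSample(net, uniformParameters(net), 500, seed = 42)
  d2 <- forwardSample(net, uniformParameters(net), 500, seed = 42)
  expect_identical(binValues(d1), binValues(d2))

  big <- forwardSample(net, uniformParameters(net), 50000, seed = 7)
  freqs <- colMeans(binValues(big))
  expect_true(all(abs(freqs - 0.5) < 0.02))

  # empirical conditional frequencies recover the generating thetas
  withr::with_seed(21, ps <- randomParameters(net, margin = 0.15))
  d <- forwardSample(net, ps, 20000, seed = 9)
  counts <- countSufficientStats(d, net)
  tab <- paramTable(ps)
  for (i in seq_len(nrow(counts))) {
    if (counts$n[i] == 0) next
    th <- tab$theta[tab$node == counts$node[i] &
                      tab$config == counts$config[i]]
    tol <- 3 * sqrt(th * (1 - th) / counts$n[i])
    expect_lt(abs(counts$k[i] / counts$n[i] - th), max(tol, 1e-9))
  }

  expect_error(forwardSample(net, sureA, 0), "positive")
})

test_that("network round-trips through the YAML config", {
  net <- buildWrkyNetwork()
  path <- tempfile(fileext = ".yaml")
  writeNetworkConfig(net, path)
  back <- readNetworkConfig(path)
  expect_equal(parentSets(back), parentSets(net))
  expect_equal(nodeLabels(back), nodeLabels(net))
  expect_equal(isComplexNode(back), isComplexNode(net))
})
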