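test_that("interventions clamp the node and leave other conditionals alone", {
  ex <- exampleDecisionNetwork()
  doA <- intervene(ex$network, ex$parameters, "A", 1)
  expect_equal(marginalProbability(doA$network, doA$parameters, c(A = 1)), 1)
  expect_equal(marginalProbability(doA$network, doA$parameters, c(B = 1)), 0.2)
  # on a root, do() coincides with conditioning
  expect_equal(
    marginalProbability(doA$network, doA$parameters, c(C = 1)),
    marginalProbability(ex$network, ex$parameters, c(C = 1), c(A = 1)))

  # non-root: do(F=1) leaves C's distribution untouched, G follows F = 1
  net <- buildWrkyNetwork()
  ps <- wrkyReferenceParameters("bayes")
  doF <- intervene(net, ps, "F", 1)
  expect_equal(parentSets(doF$network, "F"), character(0))
  expect_equal(
    marginalProbability(doF$network, doF$parameters, c(C = 1)),
    marginalProbability(net, ps, c(C = 1)))
  expect_equal(
    marginalProbability(doF$network, doF$parameters, c(G = 1)),
    getTheta(ps, "G", 1))

  expect_error(intervene(net, ps, "Z", 1), "unknown node")
  expect_error(intervene(net, ps, "F", 2), "0.*1")
})

test_that("worked-example expected utilities are exact", {
  ex <- exampleDecisionNetwork()
  eu <- function(nd, v)
    expectedUtility(ex$network, ex$parameters, nd, v, ex$utilities)$eu
  expect_equal(eu("A", 1), 90)
  expect_equal(eu("A", 0), 40)
  expect_equal(eu("B", 1), 35)
  expect_equal(eu("B", 0), 85)

  # outcome distribution over the scope sums to one, with the action's own
  # inconsistent configurations at zero
  res <- expectedUtility(ex$network, ex$parameters, "A", 1, ex$utilities)
  expect_equal(sum(res$outcome), 1, tolerance = 1e-12)
  expect_equal(unname(res$outcome["00"] + res$outcome["01"]), 0)

  expect_error(expectedUtility(ex$network, ex$parameters, "C", 1,
                               ex$utilities), "target")
})

test_that("expected utility respects affine shifts, constants and monotonicity", {
  net <- buildWrkyNetwork()
  withr::with_seed(71, ps <- randomParameters(net))
  ut <- wrkyUtilityTable()

  # constant table: EU is that constant for every action
  const <- makeUtilityTable(utilityScope(ut),
                            setNames(rep(7, 8), names(utilityValues(ut))))
  for (v in 0:1)
    expect_equal(expectedUtility(net, ps, "B", v, const)$eu, 7,
                 tolerance = 1e-12)

  # adding c to every utility adds exactly c to every EU
  shifted <- makeUtilityTable(utilityScope(ut), utilityValues(ut) + 13)
  base <- expectedUtility(net, ps, "F", 1, ut)$eu
  expect_equal(expectedUtility(net, ps, "F", 1, shifted)$eu, base + 13,
               tolerance = 1e-10)

  # raising one configuration's utility never decreases any EU
  bumped <- utilityValues(ut)
  bumped["010"] <- bumped["010"] + 25
  utBumped <- makeUtilityTable(utilityScope(ut), bumped)
  for (nd in c("A", "C", "G")) for (v in 0:1) {
    expect_gte(expectedUtility(net, ps, nd, v, utBumped)$eu,
               expectedUtility(net, ps, nd, v, ut)$eu - 1e-12)
  }
})

test_that("engine expected utilities equal the brute-force oracle", {
  net <- buildWrkyNetwork()
  ut <- wrkyUtilityTable()
  withr::with_seed(72, {
    for (rep in 1:5) {
      ps <- randomParameters(net)
      for (nd in LETTERS[1:7]) for (v in 0:1) {
        expect_equal(expectedUtility(net, ps, nd, v, ut, target = "H")$eu,
                     oracleEU(net, ps, nd, v, ut), tolerance = 1e-10)
      }
    }
  })
})

test_that("ranking orders actions by EU with a stable tie-break", {
  ex <- exampleDecisionNetwork()
  rk <- rankInterventions(ex$network, ex$parameters, ex$utilities,
                          candidates = c("A", "B"), target = "C")
  expect_equal(rk$node, c("A", "B", "A", "B"))
  expect_equal(rk$action, c(1L, 0L, 0L, 1L))
  expect_equal(rk$eu, c(90, 85, 40, 35))
  # activating gene A beats inhibiting gene B
  expect_equal(rk$node[1], "A")
  expect_equal(rk$action[1], 1L)

  # symmetric parameters give identical EUs, ordered by the tie-break
  net <- makeNetwork(list(A = character(0), B = character(0),
                          C = c("A", "B")))
  ps <- makeParameterSet(net, list(A = 0.5, B = 0.5,
                                   C = c(0.1, 0.5, 0.5, 0.9)))
  sym <- makeUtilityTable(c("A", "B"),
                          c("00" = 0, "01" = 50, "10" = 50, "11" = 100))
  rks <- rankInterventions(net, ps, sym, candidates = c("A", "B"),
                           target = "C")
  expect_equal(rks$eu[1], rks$eu[2])
  expect_equal(rks$node[1:2], c("A", "B"))  # ties broken by node id

  perNode <- attr(rk, "perNodeMax")
  expect_equal(perNode$maxEU, c(90, 85))
  expect_equal(perNode$bestAction, c(1L, 0L))
})

test_that("reference parameters reproduce the qualitative intervention ranking", {
  net <- buildWrkyNetwork()
  for (method in c("bayes", "mle")) {
    ps <- wrkyReferenceParameters(method)
    rk <- rankInterventions(net, ps, wrkyUtilityTable())
    # WRKY18 activation is the single best intervention
    expect_equal(rk$node[1], "A")
    expect_equal(rk$action[1], 1L)
    acts <- rk[rk$action == 1L, ]
    # the WRKY60-60 complex is the second-best activation
    expect_equal(acts$node[1:2], c("A", "G"))
    # the antagonists WRKY40 and WRKY40-40 score higher when inhibited
    euOf <- function(nd, v) rk$eu[rk$node == nd & rk$action == v]
    expect_gt(euOf("B", 0), euOf("B", 1))
    expect_gt(euOf("E", 0), euOf("E", 1))
  }
})

test_that("intervention reports render identically in text and CSV", {
  ex <- exampleDecisionNetwork()
  rk <- rankInterventions(ex$network, ex$parameters, ex$utilities,
                          candidates = c("A", "B"), target = "C")
  txt <- writeInterventionReport(rk, format = "text")
  csv <- writeInterventionReport(rk, format = "csv")
  expect_length(txt, 5)  # header + 4 actions
  expect_length(csv, 5)
  numsTxt <- as.numeric(sub(".* ", "", txt[-1]))
  numsCsv <- as.numeric(sub(".*,", "", csv[-1]))
  expect_equal(numsTxt, numsCsv)
  expect_equal(numsCsv, c(90, 85, 40, 35))

  empty <- rk[0, ]
  expect_silent(out <- writeInterventionReport(empty, format = "csv"))
  expect_equal(out, "node,action,eu")

  path <- tempfile(fileext = ".csv")
  writeInterventionReport(rk, path, format = "csv")
  expect_equal(readLines(path), csv)
})

test_that("utility tables build from data frames and validate", {
  df <- data.frame(G = c(1, 0), D = c(1, 0), E = c(0, 1),
                   utility = c(100, 0))
  expect_error(makeUtilityTable(c("G", "D", "E"), df), "2\\^3")
  ut <- wrkyUtilityTable()
  u <- utilityValues(ut)
  expect_equal(unname(u[c("110", "001")]), c(100, 0))
  expect_equal(utilityScope(ut), c("G", "D", "E"))
  expect_length(u, 8)
})
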