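# Independent brute-force oracle for joint / marginal / expected-utility
# computations. Deliberately written against its own data representation
# (plain named lists, enumeration over integers 0..2^N-1 via bit masks),
# sharing no code path with the package engine.

# params -> list: thetaOf[[node]][[configKey]], parentsOf[[node]]
oracleParams <- function(params) {
  tab <- paramTable(params)
  thetaOf <- list()
  for (i in seq_len(nrow(tab))) {
    nd <- tab$node[i]
    if (is.null(thetaOf[[nd]])) thetaOf[[nd]] <- list()
    thetaOf[[nd]][[paste0("c", tab$config[i])]] <- tab$theta[i]
  }
  list(theta = thetaOf, parents = params@parents)
}

# probability of one full assignment (named 0/1 vector) by explicit product
oracleJoint <- function(op, assignment) {
  p <- 1
  for (nd in names(op$parents)) {
    pa <- op$parents[[nd]]
    key <- paste0("c", paste(assignment[pa], collapse = ""))
    th <- op$theta[[nd]][[key]]
    p <- p * if (assignment[[nd]] == 1) th else 1 - th
  }
  p
}

# all 2^N assignments by bit decomposition of 0..2^N-1
oracleAssignments <- function(ids) {
  n <- length(ids)
  out <- matrix(0L, nrow = 2^n, ncol = n, dimnames = list(NULL, ids))
  for (i in 0:(2^n - 1))
    out[i + 1, ] <- (i %/% 2^(seq_len(n) - 1)) %% 2
  out
}

oracleJointVector <- function(net, params) {
  op <- oracleParams(params)
  A <- oracleAssignments(sort(nodeIds(net)))
  p <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) p[i] <- oracleJoint(op, A[i, ])
  list(assignments = A, p = p)
}

oracleMarginal <- function(net, params, query, evidence = NULL) {
  jv <- oracleJointVector(net, params)
  keepE <- rep(TRUE, nrow(jv$assignments))
  for (nd in names(evidence))
    keepE <- keepE & jv$assignments[, nd] == evidence[[nd]]
  keepQ <- keepE
  for (nd in names(query))
    keepQ <- keepQ & jv$assignments[, nd] == query[[nd]]
  sum(jv$p[keepQ]) / sum(jv$p[keepE])
}

# EU under do(node = value): mutilate the oracle's own parameter list and
# enumerate the full joint of the mutilated model.
oracleEU <- function(net, params, node, value, utable) {
  op <- oracleParams(params)
  op$parents[[node]] <- character(0)
  op$theta[[node]] <- list(c = as.numeric(value))
  A <- oracleAssignments(sort(nodeIds(net)))
  scope <- utilityScope(utable)
  u <- utilityValues(utable)
  eu <- 0
  for (i in seq_len(nrow(A))) {
    pr <- oracleJoint(op, A[i, ])
    cfg <- paste(A[i, scope], collapse = "")
    eu <- eu + pr * u[[cfg]]
  }
  eu
}

# random ParameterSet over a network, thetas uniform on (margin, 1 - margin)
randomParameters <- function(net, margin = 0) {
  thetas <- lapply(parentSets(net), function(pa) {
    k <- 2^length(pa)
    margin + runif(k) * (1 - 2 * margin)
  })
  makeParameterSet(net, thetas)
}

# write a small gene x sample expression CSV; returns the path
writeExpressionFixture <- function(values, genes, samples, path = tempfile(fileext = ".csv"),
                                   sep = ",") {
  m <- matrix(values, nrow = length(genes),
              dimnames = list(genes, samples))
  df <- data.frame(gene = genes, m, check.names = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# BinaryDataset from a plain matrix of observed (real) columns
binFixture <- function(m, prov = "real") {
  storage.mode(m) <- "integer"
  new("BinaryDataset", values = m,
      provenance = setNames(rep(prov, ncol(m)), colnames(m)))
}
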