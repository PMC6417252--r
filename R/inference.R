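# Exact inference by enumeration, and forward sampling.
#
# The WRKY network is multiply connected (A and B reconverge on H through
# C/F/G and D/E), so Pearl-style message passing is unavailable; with 8
# binary nodes the full joint has only 256 states and exact enumeration is
# the natural engine. Probabilities stay in linear space: underflow is
# impossible at this scale. Node iteration uses a fixed sorted order so
# results are bit-stable across runs.

# Full joint table: one row per assignment over all nodes (sorted ids),
# with the factorized probability. data.frame columns = node ids + `.p`.
.jointTable <- function(net, params) {
  ids <- sort(net@nodes)
  grid <- expand.grid(rep(list(0:1), length(ids)), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- ids
  p <- rep(1, nrow(grid))
  for (nd in ids) {
    pa <- params@parents[[nd]]
    sub <- params@table[params@table$node == nd, ]
    th <- if (length(pa) == 0) rep(sub$theta[sub$config == ""], nrow(grid)) else
      setNames(sub$theta, sub$config)[do.call(paste0, grid[pa])]
    if (anyNA(th))
      stop("parameter for node ", nd, " is undefined for an enumerated ",
           "configuration; substitute a Bayesian estimate first")
    p <- p * ifelse(grid[[nd]] == 1L, th, 1 - th)
  }
  grid$.p <- p
  grid
}

.asAssignment <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (length(x) == 0) return(setNames(integer(0), character(0)))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("assignments must be fully named (node id -> 0/1)")
  setNames(.checkBinary(x, "assignment value"), names(x))
}

# Logical row filter of a joint table matching a (possibly empty) assignment.
.rowsMatching <- function(grid, assignment) {
  keep <- rep(TRUE, nrow(grid))
  for (nd in names(assignment)) keep <- keep & grid[[nd]] == assignment[[nd]]
  keep
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorized joint P(x) = prod_X P(x_X | pa(x)_X) for one
#' complete configuration of all network nodes.
#'
#' @param net a [BayesNetwork].
#' @param params a [ParameterSet] for `net`.
#' @param assignment named vector/list assigning 0 or 1 to every node.
#' @return probability in \[0, 1\].
#' @examples
#' net <- buildWrkyNetwork()
#' ps <- uniformParameters(net)
#' jointProbability(net, ps, setNames(rep(1, 8), LETTERS[1:8]))  # 1/256
#' @export
jointProbability <- function(net, params, assignment) {
  stopifnot(is(net, "BayesNetwork"), is(params, "ParameterSet"))
  a <- .asAssignment(assignment)
  missing <- setdiff(net@nodes, names(a))
  if (length(missing) > 0)
    stop("assignment must cover all nodes; missing: ",
         paste(sort(missing), collapse = ", "))
  p <- 1
  for (nd in sort(net@nodes)) {
    pa <- params@parents[[nd]]
    th <- getTheta(params, nd, a[pa])
    p <- p * if (a[[nd]] == 1L) th else 1 - th
  }
  p
}

#' Exact conditional/marginal probability by enumeration
#'
#' Computes P(query | evidence) by summing the full joint table over the
#' unassigned nodes. Exact for any query on networks small enough to
#' enumerate (the WRKY network has 256 joint states).
#'
#' @param net a [BayesNetwork].
#' @param params a [ParameterSet] for `net`.
#' @param query named vector/list of node -> 0/1 (non-empty).
#' @param evidence optional named vector/list of node -> 0/1, disjoint from
#'   the query nodes.
#' @return probability in \[0, 1\].
#' @examples
#' net <- buildWrkyNetwork()
#' ps <- uniformParameters(net)
#' marginalProbability(net, ps, c(A = 1))         # 0.5
#' marginalProbability(net, ps, c(H = 1), c(A = 1))
#' @export
marginalProbability <- function(net, params, query, evidence = NULL) {
  stopifnot(is(net, "BayesNetwork"), is(params, "ParameterSet"))
  q <- .asAssignment(query)
  e <- if (is.null(evidence)) setNames(integer(0), character(0)) else
    .asAssignment(evidence)
  if (length(q) == 0) stop("query must name at least one node")
  overlap <- intersect(names(q), names(e))
  if (length(overlap) > 0)
    stop("query and evidence must be disjoint; shared: ",
         paste(overlap, collapse = ", "))
  bad <- setdiff(c(names(q), names(e)), net@nodes)
  if (length(bad) > 0) stop("unknown node id(s): ", paste(bad, collapse = ", "))
  grid <- .jointTable(net, params)
  evRows <- .rowsMatching(grid, e)
  denom <- sum(grid$.p[evRows])
  if (denom <= 0)
    stop("evidence has zero probability under the model; ",
         "conditional probability is undefined")
  sum(grid$.p[evRows & .rowsMatching(grid, q)]) / denom
}

#' Forward-sample a dataset from the network
#'
#' Draws `n` independent full assignments by sampling each node given its
#' parents in topological order. Used for parameter-recovery testing and as
#' the ground-truth generator behind [generateComposite()].
#'
#' @param net a [BayesNetwork].
#' @param params a [ParameterSet] for `net`.
#' @param n number of observations (> 0).
#' @param seed integer seed; identical seeds give identical datasets. The
#'   caller's RNG state is left untouched.
#' @return a [BinaryDataset] with all columns tagged `"synthetic"`.
#' @export
forwardSample <- function(net, params, n, seed = 1L) {
  stopifnot(is(net, "BayesNetwork"), is(params, "ParameterSet"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive count")
  n <- as.integer(n)
  ord <- .topoSort(net@parents)
  out <- matrix(NA_integer_, nrow = n, ncol = length(net@nodes),
                dimnames = list(NULL, sort(net@nodes)))
  withr::with_seed(as.integer(seed), {
    for (nd in ord) {
      pa <- params@parents[[nd]]
      sub <- params@table[params@table$node == nd, ]
      th <- if (length(pa) == 0) rep(sub$theta[sub$config == ""], n) else
        setNames(sub$theta, sub$config)[
          do.call(paste0, as.data.frame(out[, pa, drop = FALSE]))]
      if (anyNA(th)) stop("parameter for node ", nd, " is undefined")
      out[, nd] <- as.integer(runif(n) < th)
    }
  })
  new("BinaryDataset", values = out,
      provenance = setNames(rep("synthetic", ncol(out)), colnames(out)))
}
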