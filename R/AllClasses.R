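# S4 classes for the network, data, parameters and utilities.

#' BayesNetwork: a binary-node directed acyclic graphical model
#'
#' Nodes are single-character identifiers; every node is a binary random
#' variable (1 = activated, 0 = inhibited). Structure is held as a named
#' parent list. Biological labels are display metadata only: node identity
#' is always the identifier letter.
#'
#' @slot nodes character vector of node identifiers (unique).
#' @slot labels named character vector of display labels, one per node.
#' @slot isComplex named logical vector; `TRUE` for protein-complex nodes,
#'   for which no expression data exist and states must be synthesized.
#' @slot parents named list mapping each node id to the character vector of
#'   its parent ids (possibly empty).
#'
#' @seealso [buildWrkyNetwork()], [makeNetwork()], [validateStructure()]
#' @export
setClass("BayesNetwork",
  representation(
    nodes = "character",
    labels = "character",
    isComplex = "logical",
    parents = "list"
  )
)

setValidity("BayesNetwork", function(object) {
  msgs <- character(0)
  ids <- object@nodes
  if (anyDuplicated(ids)) msgs <- c(msgs, "node ids must be unique")
  if (!identical(sort(names(object@parents)), sort(ids)))
    msgs <- c(msgs, "parents list must be named by exactly the node ids")
  if (!identical(sort(names(object@labels)), sort(ids)))
    msgs <- c(msgs, "labels must be named by exactly the node ids")
  if (!identical(sort(names(object@isComplex)), sort(ids)))
    msgs <- c(msgs, "isComplex must be named by exactly the node ids")
  bad <- setdiff(unlist(object@parents), ids)
  if (length(bad) > 0)
    msgs <- c(msgs, paste0("unknown parent id(s): ", paste(bad, collapse = ", ")))
  cyc <- tryCatch({.topoSort(object@parents); NULL},
                  error = function(e) conditionMessage(e))
  if (!is.null(cyc)) msgs <- c(msgs, cyc)
  if (length(msgs) > 0) msgs else TRUE
})

#' BinaryDataset: observations by nodes matrix of binary states
#'
#' Rows are observations (samples / data points), columns are network nodes.
#' Values are 0, 1 or `NA` (missing, e.g. protein-complex columns before
#' synthesis). Each column carries a provenance tag: `"real"` for states
#' derived from expression measurements, `"synthetic"` for states produced
#' by the rule-based generator or forward sampling, `"missing"` for columns
#' not yet filled.
#'
#' @slot values integer matrix of 0/1/NA with column names = node ids.
#' @slot provenance named character vector, one tag per column.
#'
#' @seealso [binarizeExpression()], [synthesizeAll()], [forwardSample()]
#' @export
setClass("BinaryDataset",
  representation(values = "matrix", provenance = "character")
)

setValidity("BinaryDataset", function(object) {
  msgs <- character(0)
  v <- object@values
  if (is.null(colnames(v))) msgs <- c(msgs, "values must have column names")
  ok <- v %in% c(0L, 1L) | is.na(v)
  if (!all(ok)) msgs <- c(msgs, "values must be 0, 1 or NA")
  if (!identical(sort(names(object@provenance)), sort(colnames(v))))
    msgs <- c(msgs, "provenance must be named by exactly the column names")
  if (!all(object@provenance %in% c("real", "synthetic", "missing")))
    msgs <- c(msgs, "provenance tags must be 'real', 'synthetic' or 'missing'")
  if (length(msgs) > 0) msgs else TRUE
})

#' ParameterSet: one activation probability per node per parent configuration
#'
#' For every node X and every configuration of its parents, stores the
#' probability theta that X = 1. Parent configurations are encoded as binary
#' strings in parent order (`""` for root nodes, `"01"` for first parent = 0,
#' second parent = 1, ...). When produced by Bayesian estimation the table
#' also carries the posterior Beta shapes (alpha, beta) and the sufficient
#' counts (n, k); maximum-likelihood estimates for unobserved configurations
#' are flagged `undefined` with theta `NA` rather than silently set.
#'
#' @slot table data.frame with columns `node`, `config`, `theta`, `alpha`,
#'   `beta`, `n`, `k`, `undefined`.
#' @slot parents named list giving, for each node, the parent ids in the
#'   order used by the `config` encoding.
#'
#' @seealso [makeParameterSet()], [bayesianEstimate()], [mleEstimate()]
#' @export
setClass("ParameterSet",
  representation(table = "data.frame", parents = "list")
)

setValidity("ParameterSet", function(object) {
  msgs <- character(0)
  tab <- object@table
  need <- c("node", "config", "theta", "alpha", "beta", "n", "k", "undefined")
  if (!all(need %in% names(tab)))
    return(paste0("table must have columns: ", paste(need, collapse = ", ")))
  th <- tab$theta
  bad <- !is.na(th) & (th < 0 | th > 1)
  if (any(bad)) msgs <- c(msgs, "theta values must lie in [0, 1]")
  if (any(is.na(th) & !tab$undefined))
    msgs <- c(msgs, "NA theta only allowed for entries flagged undefined")
  for (nd in unique(tab$node)) {
    p <- length(object@parents[[nd]])
    rows <- tab$config[tab$node == nd]
    if (!identical(sort(rows), sort(.configsFor(p))))
      msgs <- c(msgs, paste0("node ", nd, " must have exactly 2^", p,
                             " parent configurations"))
  }
  ab <- c(tab$alpha, tab$beta)
  if (any(!is.na(ab) & ab <= 0))
    msgs <- c(msgs, "Beta shapes must be strictly positive")
  if (length(msgs) > 0) msgs else TRUE
})

#' UtilityTable: utilities over configurations of a node scope
#'
#' Maps every configuration of an ordered node scope (typically the parents
#' of the decision target) to a real-valued utility. Configurations are
#' binary strings in scope order, as in [ParameterSet].
#'
#' @slot scope ordered character vector of node ids.
#' @slot utilities named numeric vector with one entry per configuration
#'   (names are config strings; length 2^length(scope)).
#'
#' @seealso [wrkyUtilityTable()], [expectedUtility()]
#' @export
setClass("UtilityTable",
  representation(scope = "character", utilities = "numeric")
)

setValidity("UtilityTable", function(object) {
  p <- length(object@scope)
  if (anyDuplicated(object@scope)) return("scope ids must be unique")
  if (!identical(sort(names(object@utilities)), sort(.configsFor(p))))
    return(paste0("utilities must be named by all 2^", p,
                  " configurations of the scope"))
  if (any(!is.finite(object@utilities))) return("utilities must be finite")
  TRUE
})
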