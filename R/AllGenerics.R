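# Generics, accessors and show methods.

#' Node identifiers of a network or dataset
#' @param x a [BayesNetwork] or [BinaryDataset].
#' @return character vector of node ids.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "BayesNetwork", function(x) x@nodes)

#' @rdname nodeIds
#' @export
setMethod("nodeIds", "BinaryDataset", function(x) colnames(x@values))

#' Display labels of network nodes
#' @param x a [BayesNetwork].
#' @return named character vector of biological labels.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname nodeLabels
#' @export
setMethod("nodeLabels", "BayesNetwork", function(x) x@labels[x@nodes])

#' Parent sets of a network
#' @param x a [BayesNetwork].
#' @param node optional single node id; if given, that node's parent vector
#'   is returned instead of the full list.
#' @return named list of parent id vectors, or one such vector.
#' @export
setGeneric("parentSets", function(x, node) standardGeneric("parentSets"))

#' @rdname parentSets
#' @export
setMethod("parentSets", "BayesNetwork", function(x, node) {
  if (missing(node)) return(x@parents[x@nodes])
  .checkNode(x, node)
  x@parents[[node]]
})

#' Protein-complex flags of network nodes
#' @param x a [BayesNetwork].
#' @return named logical vector; `TRUE` for protein-complex nodes.
#' @export
setGeneric("isComplexNode", function(x) standardGeneric("isComplexNode"))

#' @rdname isComplexNode
#' @export
setMethod("isComplexNode", "BayesNetwork", function(x) x@isComplex[x@nodes])

#' Binary value matrix of a dataset
#' @param x a [BinaryDataset].
#' @return integer matrix (observations x nodes) of 0/1/NA.
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname binValues
#' @export
setMethod("binValues", "BinaryDataset", function(x) x@values)

#' Column provenance tags of a dataset
#' @param x a [BinaryDataset].
#' @return named character vector of "real" / "synthetic" / "missing".
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "BinaryDataset", function(x) {
  x@provenance[colnames(x@values)]
})

#' Number of observations in a dataset
#' @param x a [BinaryDataset].
#' @return integer row count.
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))

#' @rdname nObs
#' @export
setMethod("nObs", "BinaryDataset", function(x) nrow(x@values))

#' Parameter table of a ParameterSet
#' @param x a [ParameterSet].
#' @return data.frame with one row per (node, parent configuration).
#' @export
setGeneric("paramTable", function(x) standardGeneric("paramTable"))

#' @rdname paramTable
#' @export
setMethod("paramTable", "ParameterSet", function(x) x@table)

#' Activation probability for a node under a parent configuration
#'
#' @param x a [ParameterSet].
#' @param node single node id.
#' @param parentValues integer vector of the node's parent states, in the
#'   parent order recorded in the set (omit or use `integer(0)` for roots).
#' @return probability that the node is 1 under that configuration.
#' @export
setGeneric("getTheta", function(x, node, parentValues = integer(0))
  standardGeneric("getTheta"))

#' @rdname getTheta
#' @export
setMethod("getTheta", "ParameterSet", function(x, node, parentValues = integer(0)) {
  key <- paste(parentValues, collapse = "")
  row <- x@table$node == node & x@table$config == key
  if (!any(row))
    stop("no parameter entry for node ", node, " with configuration '", key, "'")
  th <- x@table$theta[row]
  if (is.na(th))
    stop("parameter for node ", node, " configuration '", key,
         "' is undefined (unobserved under MLE)")
  th
})

#' Scope of a utility table
#' @param x a [UtilityTable].
#' @return ordered character vector of node ids.
#' @export
setGeneric("utilityScope", function(x) standardGeneric("utilityScope"))

#' @rdname utilityScope
#' @export
setMethod("utilityScope", "UtilityTable", function(x) x@scope)

#' Utility values of a utility table
#' @param x a [UtilityTable].
#' @return named numeric vector (names are scope configuration strings).
#' @export
setGeneric("utilityValues", function(x) standardGeneric("utilityValues"))

#' @rdname utilityValues
#' @export
setMethod("utilityValues", "UtilityTable", function(x) {
  x@utilities[.configsFor(length(x@scope))]
})

setMethod("show", "BayesNetwork", function(object) {
  cat("BayesNetwork with", length(object@nodes), "binary nodes\n")
  for (nd in object@nodes) {
    pa <- object@parents[[nd]]
    cat(sprintf("  %s (%s)%s <- {%s}\n", nd, object@labels[[nd]],
                if (object@isComplex[[nd]]) " [complex]" else "",
                paste(pa, collapse = ",")))
  }
  invisible(NULL)
})

setMethod("show", "BinaryDataset", function(object) {
  v <- object@values
  cat("BinaryDataset:", nrow(v), "observations x", ncol(v), "nodes\n")
  tags <- vapply(colnames(v), function(cn)
    sprintf("%s[%s]", cn, object@provenance[[cn]]), character(1))
  cat("  columns:", paste(tags, collapse = " "), "\n")
  nmiss <- sum(is.na(v))
  if (nmiss > 0) cat("  missing cells:", nmiss, "\n")
  invisible(NULL)
})

setMethod("show", "ParameterSet", function(object) {
  tab <- object@table
  cat("ParameterSet:", nrow(tab), "entries over",
      length(unique(tab$node)), "nodes\n")
  lab <- parameterLabels(object)
  shown <- head(seq_len(nrow(tab)), 12L)
  for (i in shown)
    cat(sprintf("  %-18s %s\n", lab[i],
                if (is.na(tab$theta[i])) "undefined" else
                  format(round(tab$theta[i], 4))))
  if (nrow(tab) > length(shown)) cat("  ...\n")
  invisible(NULL)
})

setMethod("show", "UtilityTable", function(object) {
  cat("UtilityTable over (", paste(object@scope, collapse = ", "), ")\n",
      sep = "")
  u <- utilityValues(object)
  for (cfg in names(u)) cat(sprintf("  %s -> %g\n", cfg, u[[cfg]]))
  invisible(NULL)
})
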