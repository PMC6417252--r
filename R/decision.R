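# Decision-network inference: interventions, expected utility, ranking.
#
# An action at a node turns it from a chance node into a deterministic one:
# under do-semantics its incoming edges are severed and its distribution
# replaced by a point mass on the action value, all other conditionals
# unchanged. The expected utility of an action is
#   EU(A) = sum_i P(O_i | A) U(O_i)
# where the outcomes O_i are the configurations of the utility scope (the
# target gene's parents) and P is computed exactly in the mutilated network.

#' Construct a utility table
#'
#' @param scope ordered character vector of node ids the utilities range
#'   over (typically the decision target's parents).
#' @param utilities either a numeric vector named by configuration strings
#'   (scope order, e.g. `"110"`), or a data.frame with one column per scope
#'   node (0/1) plus a `utility` column.
#' @return a validated [UtilityTable].
#' @examples
#' makeUtilityTable(c("A", "B"),
#'                  c("10" = 100, "11" = 50, "00" = 50, "01" = 0))
#' @export
makeUtilityTable <- function(scope, utilities) {
  if (is.data.frame(utilities)) {
    if (!all(c(scope, "utility") %in% names(utilities)))
      stop("utility data.frame needs columns ",
           paste(c(scope, "utility"), collapse = ", "))
    cfg <- do.call(paste0, utilities[scope])
    utilities <- setNames(utilities$utility, cfg)
  }
  new("UtilityTable", scope = scope, utilities = utilities)
}

#' Utility table for the WRKY drought network
#'
#' Utilities at the drought-response gene H over its regulators (G, D, E).
#' The best case is both activating complexes up and the repressing complex
#' down (G=1, D=1, E=0 -> 100); the worst is the reverse (0, 0, 1 -> 0);
#' intermediate configurations score relative to those extremes.
#'
#' @return a [UtilityTable] with scope `(G, D, E)`.
#' @export
wrkyUtilityTable <- function() {
  makeUtilityTable(c("G", "D", "E"), c(
    "111" = 50, "110" = 100, "101" = 10, "100" = 50,
    "011" = 10, "010" = 50, "001" = 0, "000" = 10))
}

#' Apply a single-node intervention (do-semantics)
#'
#' Clamps one node to an action value: its incoming edges are removed and
#' its local distribution becomes a point mass on the value; every other
#' conditional is left unchanged. For root nodes this coincides with
#' conditioning.
#'
#' @param net a [BayesNetwork].
#' @param params a [ParameterSet] for `net`.
#' @param node id of the action node.
#' @param value action: 1 (activate) or 0 (inhibit).
#' @return list with the mutilated `network` and matching `parameters`.
#' @export
intervene <- function(net, params, node, value) {
  stopifnot(is(net, "BayesNetwork"), is(params, "ParameterSet"))
  .checkNode(net, node)
  value <- .checkBinary(value, "action value")
  if (length(value) != 1) stop("action value must be a single 0 or 1")
  net2 <- net
  net2@parents[[node]] <- character(0)
  tab <- params@table
  tab <- tab[tab$node != node, , drop = FALSE]
  tab <- rbind(tab, data.frame(node = node, config = "",
                               theta = as.numeric(value),
                               alpha = NA_real_, beta = NA_real_,
                               n = NA_real_, k = NA_real_, undefined = FALSE,
                               stringsAsFactors = FALSE))
  tab <- tab[order(tab$node, tab$config), ]
  rownames(tab) <- NULL
  params2 <- new("ParameterSet", table = tab,
                 parents = net2@parents[net2@nodes])
  list(network = net2, parameters = params2)
}

# Default decision target: the unique node whose parent set equals the
# utility scope (as a set), if any.
.inferTarget <- function(net, utable) {
  sc <- sort(utable@scope)
  hits <- net@nodes[vapply(net@nodes, function(nd)
    identical(sort(net@parents[[nd]]), sc), logical(1))]
  if (length(hits) == 1) hits else NULL
}

#' Expected utility of a single-node action
#'
#' Computes the exact outcome distribution over the utility-scope
#' configurations in the intervened network and returns the
#' probability-weighted utility sum. If the action node lies inside the
#' scope, outcomes inconsistent with the action have probability zero and
#' drop out of the sum automatically.
#'
#' @param net a [BayesNetwork].
#' @param params a [ParameterSet] for `net`.
#' @param node action node id (must not be the decision target).
#' @param value action: 1 (activate) or 0 (inhibit).
#' @param utable a [UtilityTable].
#' @param target decision-target node id; inferred as the node whose parents
#'   are exactly the utility scope when omitted. Intervening on the target
#'   is an error.
#' @return list of class `"InterventionResult"` with elements `node`,
#'   `action`, `eu` and `outcome` (named probability vector over scope
#'   configurations, summing to 1).
#' @examples
#' ex <- exampleDecisionNetwork()
#' expectedUtility(ex$network, ex$parameters, "A", 1, ex$utilities)$eu  # 90
#' @export
expectedUtility <- function(net, params, node, value, utable, target = NULL) {
  stopifnot(is(utable, "UtilityTable"))
  if (is.null(target)) target <- .inferTarget(net, utable)
  if (!is.null(target) && identical(node, target))
    stop("cannot intervene on the decision target node ", target)
  miss <- setdiff(utable@scope, net@nodes)
  if (length(miss) > 0)
    stop("utility scope node(s) not in network: ", paste(miss, collapse = ", "))
  mut <- intervene(net, params, node, value)
  grid <- .jointTable(mut$network, mut$parameters)
  u <- utilityValues(utable)
  outcome <- vapply(names(u), function(cfg) {
    states <- as.integer(strsplit(cfg, "")[[1]])
    sum(grid$.p[.rowsMatching(grid, setNames(states, utable@scope))])
  }, numeric(1))
  structure(list(node = node, action = value,
                 eu = sum(outcome * u), outcome = outcome),
            class = "InterventionResult")
}

#' Rank all single-node interventions by expected utility
#'
#' Evaluates both actions (activate and inhibit) for every candidate node
#' and sorts by expected utility, descending, with a stable tie-break by
#' (node id, action). The per-node maximum over the two actions — the
#' "maximum expected utility" of a node — is attached as an attribute.
#'
#' @param net a [BayesNetwork].
#' @param params a [ParameterSet] for `net`.
#' @param utable a [UtilityTable].
#' @param candidates node ids to consider; defaults to every node except
#'   the decision target.
#' @param target decision-target node id (see [expectedUtility()]).
#' @return data.frame with columns `node`, `action`, `eu`, ordered by
#'   decreasing `eu`; attributes `"perNodeMax"` (data.frame of node,
#'   bestAction, maxEU) and `"outcomes"` (list of outcome distributions).
#' @export
rankInterventions <- function(net, params, utable, candidates = NULL,
                              target = NULL) {
  if (is.null(target)) target <- .inferTarget(net, utable)
  if (is.null(candidates)) candidates <- setdiff(net@nodes, target)
  if (length(candidates) == 0) stop("no candidate nodes")
  res <- list()
  for (nd in sort(candidates)) for (ac in c(1L, 0L))
    res[[paste0(nd, ac)]] <-
      expectedUtility(net, params, nd, ac, utable, target = target)
  df <- data.frame(node = vapply(res, `[[`, character(1), "node"),
                   action = vapply(res, `[[`, integer(1), "action"),
                   eu = vapply(res, `[[`, numeric(1), "eu"),
                   stringsAsFactors = FALSE)
  ord <- order(-df$eu, df$node, df$action)
  df <- df[ord, ]
  rownames(df) <- NULL
  perNode <- do.call(rbind, lapply(sort(unique(df$node)), function(nd) {
    sub <- df[df$node == nd, ]
    best <- sub[which.max(sub$eu), ]
    data.frame(node = nd, bestAction = best$action, maxEU = best$eu,
               stringsAsFactors = FALSE)
  }))
  attr(df, "perNodeMax") <- perNode[order(-perNode$maxEU, perNode$node), ]
  attr(df, "outcomes") <- lapply(res, `[[`, "outcome")[ord]
  df
}

#' Render an intervention ranking as text or CSV
#'
#' @param results ranking data.frame from [rankInterventions()] (possibly
#'   empty).
#' @param path optional output file; when `NULL` the rendering is returned
#'   only.
#' @param format `"text"` or `"csv"`; both carry identical numbers.
#' @param labels optional named character vector of node labels to display.
#' @return (invisibly) the character rendering, one element per line.
#' @export
writeInterventionReport <- function(results, path = NULL,
                                    format = c("text", "csv"),
                                    labels = NULL) {
  format <- match.arg(format)
  act <- function(a) ifelse(a == 1, "activate", "inhibit")
  nm <- function(nd) if (is.null(labels)) nd else
    paste0(nd, " (", labels[nd], ")")
  if (nrow(results) == 0) {
    lines <- if (format == "csv") "node,action,eu" else character(0)
  } else if (format == "csv") {
    lines <- c("node,action,eu",
               sprintf("%s,%s,%.10g", results$node, act(results$action),
                       results$eu))
  } else {
    lines <- c(sprintf("%-28s %-9s %12s", "node", "action", "EU"),
               sprintf("%-28s %-9s %12.4f", nm(results$node),
                       act(results$action), results$eu))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Bar chart of per-node activation and inhibition utilities
#'
#' One pair of bars per node: expected utility of activating versus
#' inhibiting it. Requires ggplot2.
#'
#' @param results ranking data.frame from [rankInterventions()].
#' @return a ggplot object.
#' @export
plotInterventionUtilities <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- results
  df$action <- ifelse(df$action == 1, "activation", "inhibition")
  ggplot2::ggplot(df, ggplot2::aes(x = node, y = eu, fill = action)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(activation = "firebrick",
                                          inhibition = "grey20")) +
    ggplot2::labs(x = "node", y = "expected utility", fill = NULL) +
    ggplot2::theme_minimal()
}
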