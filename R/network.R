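# Network construction and structural validation.

# Kahn topological sort over a named parent list; errors on cycles.
.topoSort <- function(parents) {
  ids <- names(parents)
  indeg <- vapply(parents, length, integer(1))
  children <- lapply(setNames(ids, ids), function(p)
    ids[vapply(parents, function(pa) p %in% pa, logical(1))])
  queue <- sort(ids[indeg == 0])
  out <- character(0)
  while (length(queue) > 0) {
    nd <- queue[1]; queue <- queue[-1]
    out <- c(out, nd)
    for (ch in children[[nd]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- sort(c(queue, ch))
    }
  }
  if (length(out) < length(ids)) {
    cyc <- setdiff(ids, out)
    stop("directed cycle detected among nodes: ", paste(sort(cyc), collapse = ", "))
  }
  out
}

# All parent configurations for p parents, as binary strings in increasing
# binary order; character position i is the state of parent i.
.configsFor <- function(p) {
  if (p == 0) return("")
  sort(apply(expand.grid(rep(list(0:1), p)), 1L, paste, collapse = ""))
}

.checkNode <- function(net, node) {
  if (length(node) != 1 || !node %in% net@nodes)
    stop("unknown node id: ", paste(node, collapse = ", "))
  invisible(node)
}

.checkBinary <- function(x, what = "value") {
  if (any(!x %in% c(0, 1)))
    stop(what, " must be 0 (inhibition) or 1 (activation)")
  invisible(as.integer(x))
}

#' Construct a binary-node Bayesian network
#'
#' @param parents named list mapping each node id to its parent ids.
#' @param labels optional named character vector of display labels
#'   (defaults to the ids themselves).
#' @param isComplex optional named logical vector flagging protein-complex
#'   nodes (defaults to all `FALSE`).
#' @return a validated [BayesNetwork].
#' @examples
#' chain <- makeNetwork(list(A = character(0), B = "A"))
#' parentSets(chain, "B")
#' @export
makeNetwork <- function(parents, labels = NULL, isComplex = NULL) {
  ids <- names(parents)
  if (is.null(ids) || any(ids == ""))
    stop("parents must be a fully named list")
  parents <- lapply(parents, as.character)
  if (is.null(labels)) labels <- setNames(ids, ids)
  if (is.null(isComplex)) isComplex <- setNames(rep(FALSE, length(ids)), ids)
  new("BayesNetwork", nodes = ids, labels = labels,
      isComplex = isComplex, parents = parents)
}

# Default display labels for the WRKY network. C and D are protein complexes
# whose exact composition is read off the pathway diagram, hence overridable.
.wrkyDefaultLabels <- c(
  A = "WRKY18", B = "WRKY40", C = "WRKY18-40 complex", D = "WRKY18-18 complex",
  E = "WRKY40-40 complex", F = "WRKY60", G = "WRKY60-60 complex",
  H = "drought-response gene"
)

#' Build the WRKY drought-pathway Bayesian network
#'
#' The fixed eight-node structure of the ABA-induced WRKY signaling pathway:
#' transcription factors WRKY18 (A), WRKY40 (B) and WRKY60 (F), the
#' drought-response gene (H), and the four protein-complex nodes C, D, E, G.
#' Parent sets are A:\{\}, B:\{\}, C:\{A,B\}, D:\{A\}, E:\{B\}, F:\{C\},
#' G:\{F\}, H:\{D,E,G\}.
#'
#' Node identity is the letter; biological labels are display metadata only
#' and can be overridden (e.g. for alternative complex naming).
#'
#' @param labels optional named character vector overriding default labels
#'   for a subset of nodes.
#' @return a [BayesNetwork] with 8 nodes, 4 of them protein complexes.
#' @examples
#' net <- buildWrkyNetwork()
#' parentSets(net, "H")
#' @export
buildWrkyNetwork <- function(labels = NULL) {
  lab <- .wrkyDefaultLabels
  if (!is.null(labels)) {
    bad <- setdiff(names(labels), names(lab))
    if (length(bad) > 0) stop("unknown node id(s) in labels: ",
                              paste(bad, collapse = ", "))
    lab[names(labels)] <- labels
  }
  makeNetwork(
    parents = list(
      A = character(0), B = character(0), C = c("A", "B"), D = "A",
      E = "B", F = "C", G = "F", H = c("D", "E", "G")
    ),
    labels = lab,
    isComplex = c(A = FALSE, B = FALSE, C = TRUE, D = TRUE,
                  E = TRUE, F = FALSE, G = TRUE, H = FALSE)
  )
}

#' Validate a network structure
#'
#' Checks acyclicity (raising an error that names the offending cycle),
#' weak connectedness, and reachability of the decision target: any node
#' with no directed path to the target is reported, since interventions on
#' it cannot move the target's distribution.
#'
#' @param net a [BayesNetwork].
#' @param target node id of the utility/decision target; defaults to the
#'   sink nodes (nodes without children).
#' @return (invisibly) a list with elements `acyclic`, `connected`,
#'   `isolated` (ids with neither parents nor children), `unreachable`
#'   (ids with no path to the target) and `topologicalOrder`. Isolated or
#'   unreachable nodes trigger warnings.
#' @export
validateStructure <- function(net, target = NULL) {
  stopifnot(is(net, "BayesNetwork"))
  ord <- .topoSort(net@parents)  # errors on cycles, naming them
  ids <- net@nodes
  hasChild <- vapply(ids, function(p)
    any(vapply(net@parents, function(pa) p %in% pa, logical(1))), logical(1))
  if (is.null(target)) target <- ids[!hasChild]
  isolated <- ids[!hasChild & vapply(net@parents[ids], length, integer(1)) == 0]
  isolated <- setdiff(isolated, target)
  # ancestors of the target(s), found by walking parent links
  reach <- unique(target)
  repeat {
    more <- setdiff(unique(unlist(net@parents[reach])), reach)
    if (length(more) == 0) break
    reach <- c(reach, more)
  }
  unreachable <- setdiff(ids, reach)
  connected <- length(isolated) == 0
  if (length(isolated) > 0)
    warning("isolated node(s) with no edges: ", paste(isolated, collapse = ", "))
  if (length(unreachable) > 0)
    warning("node(s) with no path to the target: ",
            paste(sort(unreachable), collapse = ", "))
  invisible(list(acyclic = TRUE, connected = connected, isolated = isolated,
                 unreachable = sort(unreachable), topologicalOrder = ord))
}

#' Construct a ParameterSet from per-node theta vectors
#'
#' @param net a [BayesNetwork].
#' @param thetas named list; for each node either a single probability (root)
#'   or a numeric vector named by parent-configuration strings (or unnamed in
#'   increasing binary configuration order).
#' @return a validated [ParameterSet].
#' @examples
#' net <- makeNetwork(list(A = character(0), B = "A"))
#' ps <- makeParameterSet(net, list(A = 0.7, B = c("0" = 0.1, "1" = 0.9)))
#' getTheta(ps, "B", 1)
#' @export
makeParameterSet <- function(net, thetas) {
  stopifnot(is(net, "BayesNetwork"))
  missing <- setdiff(net@nodes, names(thetas))
  if (length(missing) > 0)
    stop("missing theta entries for node(s): ", paste(missing, collapse = ", "))
  rows <- lapply(net@nodes, function(nd) {
    cfgs <- .configsFor(length(net@parents[[nd]]))
    th <- thetas[[nd]]
    if (is.null(names(th))) {
      if (length(th) != length(cfgs))
        stop("node ", nd, " needs ", length(cfgs), " theta value(s)")
      names(th) <- cfgs
    }
    if (!all(cfgs %in% names(th)))
      stop("node ", nd, " is missing configuration(s): ",
           paste(setdiff(cfgs, names(th)), collapse = ", "))
    # match() rather than name indexing: "" is a valid config key for roots
    data.frame(node = nd, config = cfgs,
               theta = as.numeric(th[match(cfgs, names(th))]),
               alpha = NA_real_, beta = NA_real_, n = NA_real_, k = NA_real_,
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  new("ParameterSet", table = do.call(rbind, rows),
      parents = net@parents[net@nodes])
}

#' Uniform ParameterSet (all thetas equal)
#'
#' @param net a [BayesNetwork].
#' @param theta common activation probability (default 0.5).
#' @return a [ParameterSet].
#' @export
uniformParameters <- function(net, theta = 0.5) {
  makeParameterSet(net, setNames(lapply(net@nodes, function(nd)
    rep(theta, 2^length(net@parents[[nd]]))), net@nodes))
}

#' Human-readable labels for ParameterSet entries
#'
#' Formats entries in conditional-probability notation, e.g. `P(A1)` for a
#' root marginal and `P(C1 |A1,B0)` for a conditional entry.
#'
#' @param params a [ParameterSet].
#' @return character vector aligned with the rows of [paramTable()].
#' @export
parameterLabels <- function(params) {
  tab <- params@table
  vapply(seq_len(nrow(tab)), function(i) {
    nd <- tab$node[i]
    pa <- params@parents[[nd]]
    if (length(pa) == 0) return(sprintf("P(%s1)", nd))
    states <- strsplit(tab$config[i], "")[[1]]
    sprintf("P(%s1 |%s)", nd, paste0(pa, states, collapse = ","))
  }, character(1))
}
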