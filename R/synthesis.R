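# Rule-based synthesis of protein-complex node states.
#
# No expression data exist for the protein-complex nodes C, D, E, G, so
# their binary states are generated from the observed states of their
# parents and children in the network. Configurations in which the observed
# neighbours are fully consistent with one complex state are set
# deterministically; ambiguous configurations are assigned probabilistically:
# the favoured value v is drawn with a probability p sampled uniformly from
# a discrete set (default {0.6, 0.7, 0.8, 0.9, 1.0}), else 1 - v.

#' Default discrete assignment-probability set
#'
#' The probabilities from which each probabilistic assignment draws, each
#' equally likely. All members must exceed 0.5 (the favoured value must stay
#' favoured) and be at most 1. Mean 0.8, so the long-run frequency of the
#' favoured value on assignment rows is 0.8.
#'
#' @return numeric vector `c(0.6, 0.7, 0.8, 0.9, 1.0)`.
#' @export
defaultAssignProbs <- function() c(0.6, 0.7, 0.8, 0.9, 1.0)

.checkAssignProbs <- function(probs) {
  if (!is.numeric(probs) || length(probs) == 0 ||
      any(probs <= 0.5 | probs > 1))
    stop("assignment probabilities must lie in (0.5, 1]")
  probs
}

#' Construct a complex-node rule table
#'
#' @param node the complex node id the table generates.
#' @param conditioning observed node ids the rules condition on (the complex
#'   node's parents and children in the network), in config-string order.
#' @param rules data.frame with columns `config` (binary string over the
#'   conditioning nodes), `type` (`"det"` or `"assign"`) and `value` (0/1:
#'   the fixed value for `det`, the favoured value for `assign`). Must cover
#'   every configuration exactly once.
#' @return a list of class `"ComplexRuleTable"`.
#' @export
complexRuleTable <- function(node, conditioning, rules) {
  cfgs <- .configsFor(length(conditioning))
  if (!identical(sort(rules$config), sort(cfgs)))
    stop("rules must cover every configuration of (",
         paste(conditioning, collapse = ","), ") exactly once")
  if (!all(rules$type %in% c("det", "assign")))
    stop("rule type must be 'det' or 'assign'")
  .checkBinary(rules$value, "rule value")
  structure(list(node = node, conditioning = conditioning,
                 rules = rules[match(cfgs, rules$config), , drop = FALSE]),
            class = "ComplexRuleTable")
}

.rt <- function(node, cond, config, type, value) {
  complexRuleTable(node, cond, data.frame(
    config = config, type = type, value = value, stringsAsFactors = FALSE))
}

#' Rule tables for the WRKY protein-complex nodes
#'
#' The generation rules for nodes C, D, E and G. D conditions on (A, H):
#' agreement of parent and child with an active/inactive complex is
#' deterministic, disagreement is a probabilistic assignment of the
#' parent-implied value. E conditions on (B, H) with the roles reversed
#' (B represses H through E), G on (F, H) like D, and C on its parents and
#' child (A, B, F) with majority-consistency assignments.
#'
#' @return named list of [complexRuleTable()] objects for C, D, E, G.
#' @export
wrkyRuleTables <- function() {
  list(
    C = .rt("C", c("A", "B", "F"),
            config = c("000", "001", "010", "011", "100", "101", "110", "111"),
            type   = c("det", "assign", "assign", "assign",
                       "assign", "assign", "assign", "det"),
            value  = c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L)),
    D = .rt("D", c("A", "H"),
            config = c("00", "01", "10", "11"),
            type   = c("det", "assign", "assign", "det"),
            value  = c(0L, 0L, 1L, 1L)),
    E = .rt("E", c("B", "H"),
            config = c("00", "01", "10", "11"),
            type   = c("assign", "det", "det", "assign"),
            value  = c(0L, 0L, 1L, 1L)),
    G = .rt("G", c("F", "H"),
            config = c("00", "01", "10", "11"),
            type   = c("det", "assign", "assign", "det"),
            value  = c(0L, 0L, 1L, 1L))
  )
}

# Deterministic per-node seed stream derived from a run-level seed, so that
# the order in which complex columns are synthesized never changes draws.
.nodeSeed <- function(seed, node) {
  (as.integer(seed) %% 1000003L) * 1009L + utf8ToInt(substr(node, 1, 1))
}

#' Synthesize one protein-complex column
#'
#' Fills the target column row by row from its rule table: deterministic
#' configurations are set exactly; an `assign` configuration with favoured
#' value v draws p uniformly from `probs` (fresh draw per observation by
#' default) and sets v with probability p, else 1 - v.
#'
#' @param data a [BinaryDataset] whose conditioning columns are fully
#'   observed and whose target column is absent or all-missing.
#' @param rules a [complexRuleTable()] for the target node.
#' @param probs discrete assignment-probability set
#'   (default [defaultAssignProbs()]).
#' @param seed run-level integer seed.
#' @param drawPerRow draw a fresh p per observation (default, the
#'   per-assignment-event reading) or one p per node run (`FALSE`).
#' @return the dataset with the target column filled and tagged
#'   `"synthetic"`.
#' @export
synthesizeComplexColumn <- function(data, rules, probs = defaultAssignProbs(),
                                    seed = 1L, drawPerRow = TRUE) {
  stopifnot(is(data, "BinaryDataset"), inherits(rules, "ComplexRuleTable"))
  .checkAssignProbs(probs)
  v <- data@values
  node <- rules$node
  miss <- setdiff(rules$conditioning, colnames(v))
  if (length(miss) > 0)
    stop("conditioning column(s) missing from dataset: ",
         paste(miss, collapse = ", "))
  if (any(is.na(v[, rules$conditioning])))
    stop("conditioning columns must be fully observed")
  if (node %in% colnames(v) && !all(is.na(v[, node])))
    stop("target column ", node,
         " already has values; refusing to overwrite")
  key <- do.call(paste0, as.data.frame(v[, rules$conditioning, drop = FALSE]))
  idx <- match(key, rules$rules$config)
  type <- rules$rules$type[idx]
  fav <- rules$rules$value[idx]
  out <- fav  # deterministic rows are exactly the favoured value
  assign <- which(type == "assign")
  if (length(assign) > 0) {
    draws <- withr::with_seed(.nodeSeed(seed, node), {
      p <- if (drawPerRow) sample(probs, length(assign), replace = TRUE) else
        rep(sample(probs, 1L), length(assign))
      runif(length(assign)) < p
    })
    out[assign] <- ifelse(draws, fav[assign], 1L - fav[assign])
  }
  if (!node %in% colnames(v)) {
    v <- cbind(v, matrix(out, ncol = 1, dimnames = list(NULL, node)))
  } else v[, node] <- out
  prov <- data@provenance
  prov[node] <- "synthetic"
  new("BinaryDataset", values = v[, sort(colnames(v)), drop = FALSE],
      provenance = prov)
}

#' Synthesize all protein-complex columns
#'
#' Fills C, D, E and G from their rule tables. Each complex node conditions
#' only on observed non-complex columns (A, B, F, H), so synthesis order is
#' irrelevant; per-node seed streams keep draws identical regardless.
#'
#' @param data a [BinaryDataset] with columns A, B, F, H observed.
#' @param net a [BayesNetwork] (used to identify the complex nodes;
#'   default [buildWrkyNetwork()]).
#' @param ruleTables named list of rule tables (default [wrkyRuleTables()]).
#' @inheritParams synthesizeComplexColumn
#' @return a complete [BinaryDataset] with no missing values.
#' @export
synthesizeAll <- function(data, net = buildWrkyNetwork(),
                          ruleTables = wrkyRuleTables(),
                          probs = defaultAssignProbs(), seed = 1L,
                          drawPerRow = TRUE) {
  stopifnot(is(data, "BinaryDataset"))
  for (nd in sort(names(ruleTables)))
    data <- synthesizeComplexColumn(data, ruleTables[[nd]], probs = probs,
                                    seed = seed, drawPerRow = drawPerRow)
  if (any(is.na(data@values)))
    stop("missing values remain after synthesis")
  data
}

#' Generate a composite dataset with known ground truth
#'
#' End-to-end fixture generator: forward-samples a complete dataset from a
#' known [ParameterSet], then rebuilds the pipeline view of it — the
#' non-complex columns A, B, F, H kept as observed (tagged `"real"`) and
#' the complex columns C, D, E, G re-synthesized from the rule tables.
#' Supports parameter-recovery and procedure-consistency testing.
#'
#' @param net a [BayesNetwork] (default [buildWrkyNetwork()]).
#' @param params generating [ParameterSet].
#' @param n number of observations (> 0).
#' @param seed integer seed driving both sampling and synthesis.
#' @inheritParams synthesizeAll
#' @return list with elements `truth` (the fully sampled [BinaryDataset])
#'   and `composite` (the pipeline-style dataset).
#' @export
generateComposite <- function(net = buildWrkyNetwork(), params, n, seed = 1L,
                              ruleTables = wrkyRuleTables(),
                              probs = defaultAssignProbs()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive count")
  truth <- forwardSample(net, params, n, seed = seed)
  complexIds <- names(ruleTables)
  keep <- setdiff(colnames(truth@values), complexIds)
  observed <- new("BinaryDataset",
                  values = truth@values[, keep, drop = FALSE],
                  provenance = setNames(rep("real", length(keep)), keep))
  composite <- synthesizeAll(observed, net, ruleTables = ruleTables,
                             probs = probs, seed = seed)
  list(truth = truth, composite = composite)
}
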