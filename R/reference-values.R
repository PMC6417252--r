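# Bundled reference parameter sets and the worked three-node example.

#' Reference parameter estimates for the WRKY network
#'
#' The marginal and conditional activation probabilities estimated for the
#' WRKY drought network from the composite expression dataset, by Bayesian
#' (Beta(1,1) posterior mean) and maximum-likelihood estimation. Useful for
#' demonstrations, demo-mode pipeline runs and qualitative ranking checks
#' without re-running estimation.
#'
#' The drought-response gene H is a leaf and the utility scope is its parent
#' set (G, D, E), so H's own conditional probabilities cancel out of every
#' intervention's outcome distribution; they are filled with the
#' uninformative value 0.5 here and marked as such.
#'
#' @param method `"bayes"` (default) or `"mle"`.
#' @return a [ParameterSet] for [buildWrkyNetwork()].
#' @export
wrkyReferenceParameters <- function(method = c("bayes", "mle")) {
  method <- match.arg(method)
  bayes <- list(
    A = 0.50,
    B = 0.466,
    C = c("00" = 0.13, "01" = 0.625, "10" = 0.60, "11" = 0.905),
    D = c("0" = 0.10, "1" = 0.983),
    E = c("0" = 0.093, "1" = 0.857),
    F = c("0" = 0.196, "1" = 0.766),
    G = c("0" = 0.117, "1" = 0.867),
    H = rep(0.5, 8)  # leaf CPT; inert for parent-scope utility ranking
  )
  mle <- list(
    A = 0.50,
    B = 0.465,
    C = c("00" = 0.113, "01" = 0.645, "10" = 0.611, "11" = 0.925),
    D = c("0" = 0.086, "1" = 1.0),
    E = c("0" = 0.080, "1" = 0.870),
    F = c("0" = 0.185, "1" = 0.774),
    G = c("0" = 0.103, "1" = 0.879),
    H = rep(0.5, 8)
  )
  makeParameterSet(buildWrkyNetwork(),
                   if (method == "bayes") bayes else mle)
}

#' The three-node worked example decision network
#'
#' A minimal decision network used to illustrate utility-based inference:
#' independent root genes A (P(A=1) = 0.7) and B (P(B=1) = 0.2) jointly
#' regulate gene C — A activates it, B inhibits it. The goal is C active,
#' scored by a utility table over (A, B): the best case (A=1, B=0) scores
#' 100, the worst (A=0, B=1) scores 0, mixed cases 50. C's own conditional
#' distribution does not enter the expected-utility computation (the scope
#' is its parents); the one bundled is illustrative.
#'
#' @return list with elements `network` ([BayesNetwork]), `parameters`
#'   ([ParameterSet]) and `utilities` ([UtilityTable]).
#' @examples
#' ex <- exampleDecisionNetwork()
#' expectedUtility(ex$network, ex$parameters, "A", 1, ex$utilities)$eu
#' @export
exampleDecisionNetwork <- function() {
  net <- makeNetwork(
    parents = list(A = character(0), B = character(0), C = c("A", "B")),
    labels = c(A = "gene A", B = "gene B", C = "gene C"))
  params <- makeParameterSet(net, list(
    A = 0.7, B = 0.2,
    # illustrative: A activates C, B inhibits C
    C = c("00" = 0.5, "01" = 0.05, "10" = 0.95, "11" = 0.5)))
  utable <- makeUtilityTable(c("A", "B"),
                             c("10" = 100, "11" = 50, "00" = 50, "01" = 0))
  list(network = net, parameters = params, utilities = utable)
}
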