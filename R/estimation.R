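# Parameter estimation: sufficient counts, conjugate Beta-Binomial
# posterior means, and maximum likelihood.
#
# Each node's state given its parents is Bernoulli, so n observations of a
# parent configuration with k activations give a Binomial likelihood. A
# Beta(alpha, beta) prior is conjugate: the posterior is
# Beta(alpha + k, beta + n - k) and its mean (alpha + k)/(alpha + beta + n)
# is the point estimate. With the uniform Beta(1, 1) prior this is
# (k + 1)/(n + 2), strictly inside (0, 1) for any finite data — zero
# probability estimates can only come from true non-occurrence in the
# limit. The MLE is the raw ratio k/n and can reach the boundary, or be
# undefined when a parent configuration never occurs.

#' Sufficient counts per node and parent configuration
#'
#' For every node X and every configuration of its parents, counts n (rows
#' with that configuration) and k (those rows with X = 1). These counts are
#' the complete sufficient statistics for both estimators.
#'
#' @param data a complete [BinaryDataset] (no missing values; run
#'   [synthesizeAll()] first if complex columns are missing).
#' @param net a [BayesNetwork] whose nodes are columns of `data`.
#' @return data.frame of class `"SufficientCounts"` with columns `node`,
#'   `config`, `n`, `k`; the parent list is attached as attribute
#'   `"parents"`. Per node, the `n` column sums to the observation count.
#' @export
countSufficientStats <- function(data, net) {
  stopifnot(is(data, "BinaryDataset"), is(net, "BayesNetwork"))
  v <- data@values
  miss <- setdiff(net@nodes, colnames(v))
  if (length(miss) > 0)
    stop("dataset is missing node column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(v[, net@nodes])))
    stop("dataset has missing values; synthesize complex columns first ",
         "(see synthesizeAll)")
  rows <- lapply(sort(net@nodes), function(nd) {
    pa <- net@parents[[nd]]
    cfgs <- .configsFor(length(pa))
    key <- if (length(pa) == 0) rep("", nrow(v)) else
      do.call(paste0, as.data.frame(v[, pa, drop = FALSE]))
    n <- vapply(cfgs, function(cf) sum(key == cf), numeric(1))
    k <- vapply(cfgs, function(cf) sum(v[key == cf, nd]), numeric(1))
    data.frame(node = nd, config = cfgs, n = n, k = k,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "parents") <- net@parents[net@nodes]
  class(out) <- c("SufficientCounts", "data.frame")
  out
}

.checkCounts <- function(counts) {
  if (!inherits(counts, "SufficientCounts"))
    stop("counts must come from countSufficientStats()")
  counts
}

#' Bayesian (Beta-Binomial) parameter estimation
#'
#' Conjugate updating per entry: posterior shapes alpha' = alpha + k,
#' beta' = beta + n - k; the point estimate is the posterior mean
#' alpha'/(alpha' + beta'). Estimates are strictly inside (0, 1) for any
#' finite dataset, including configurations never observed (pure prior).
#'
#' @param counts a `"SufficientCounts"` table from [countSufficientStats()].
#' @param prior either a length-2 numeric `c(alpha, beta)` applied to every
#'   entry (default the uniform `c(1, 1)`), or a data.frame with columns
#'   `node`, `config`, `alpha`, `beta` for per-entry priors.
#' @return a [ParameterSet] carrying posterior shapes and counts.
#' @examples
#' net <- buildWrkyNetwork()
#' d <- forwardSample(net, uniformParameters(net), 100, seed = 7)
#' bayesianEstimate(countSufficientStats(d, net))
#' @export
bayesianEstimate <- function(counts, prior = c(1, 1)) {
  .checkCounts(counts)
  if (is.data.frame(prior)) {
    key <- paste(counts$node, counts$config)
    pkey <- paste(prior$node, prior$config)
    idx <- match(key, pkey)
    if (anyNA(idx)) stop("per-entry prior is missing entries: ",
                         paste(key[is.na(idx)], collapse = "; "))
    a <- prior$alpha[idx]; b <- prior$beta[idx]
  } else {
    if (length(prior) != 2) stop("prior must be c(alpha, beta)")
    a <- rep(prior[1], nrow(counts)); b <- rep(prior[2], nrow(counts))
  }
  if (any(a <= 0 | b <= 0)) stop("prior shapes must be strictly positive")
  a1 <- a + counts$k
  b1 <- b + counts$n - counts$k
  tab <- data.frame(node = counts$node, config = counts$config,
                    theta = a1 / (a1 + b1), alpha = a1, beta = b1,
                    n = counts$n, k = counts$k, undefined = FALSE,
                    stringsAsFactors = FALSE)
  new("ParameterSet", table = tab, parents = attr(counts, "parents"))
}

#' Maximum-likelihood parameter estimation
#'
#' Per entry, theta = k/n. A parent configuration with no observations has
#' no MLE; such entries are flagged `undefined` (theta `NA`) and reported,
#' never silently set to 0 or 0.5. Downstream inference refuses undefined
#' entries; the pipeline substitutes the Bayesian estimate and logs it.
#'
#' @param counts a `"SufficientCounts"` table from [countSufficientStats()].
#' @return a [ParameterSet]; a message lists any undefined entries.
#' @export
mleEstimate <- function(counts) {
  .checkCounts(counts)
  undef <- counts$n == 0
  tab <- data.frame(node = counts$node, config = counts$config,
                    theta = ifelse(undef, NA_real_, counts$k / counts$n),
                    alpha = NA_real_, beta = NA_real_,
                    n = counts$n, k = counts$k, undefined = undef,
                    stringsAsFactors = FALSE)
  ps <- new("ParameterSet", table = tab, parents = attr(counts, "parents"))
  if (any(undef))
    message("MLE undefined (no observations) for: ",
            paste(parameterLabels(ps)[undef], collapse = ", "))
  ps
}

#' Compare Bayesian and MLE parameter estimates
#'
#' Entry-by-entry comparison of two estimates over the same structure,
#' formatted in conditional-probability notation (one row per local
#' probability, one column per method).
#'
#' @param bayes,mle [ParameterSet] objects over the same structure.
#' @return data.frame with columns `probability` (label), `bayes`, `mle`
#'   and `difference` (absolute); the maximum difference over defined
#'   entries is attached as attribute `"maxDifference"`.
#' @export
compareEstimates <- function(bayes, mle) {
  stopifnot(is(bayes, "ParameterSet"), is(mle, "ParameterSet"))
  bt <- bayes@table; mt <- mle@table
  if (!identical(bt[c("node", "config")], mt[c("node", "config")]) ||
      !identical(bayes@parents, mle@parents))
    stop("parameter sets are over different structures")
  diff <- abs(bt$theta - mt$theta)
  out <- data.frame(probability = parameterLabels(bayes),
                    bayes = bt$theta, mle = mt$theta, difference = diff,
                    stringsAsFactors = FALSE)
  attr(out, "maxDifference") <-
    if (all(is.na(diff))) NA_real_ else max(diff, na.rm = TRUE)
  out
}

#' Substitute Bayesian estimates for undefined MLE entries
#'
#' @param mle a [ParameterSet] possibly containing undefined entries.
#' @param bayes a [ParameterSet] over the same structure providing the
#'   fallback values.
#' @return the MLE set with undefined thetas replaced; a message lists the
#'   substitutions made.
#' @export
fillUndefined <- function(mle, bayes) {
  stopifnot(is(mle, "ParameterSet"), is(bayes, "ParameterSet"))
  undef <- mle@table$undefined
  if (!any(undef)) return(mle)
  key <- paste(mle@table$node, mle@table$config)
  bkey <- paste(bayes@table$node, bayes@table$config)
  mle@table$theta[undef] <- bayes@table$theta[match(key[undef], bkey)]
  mle@table$undefined[undef] <- FALSE
  message("substituted Bayesian estimates for ",
          sum(undef), " undefined MLE entr",
          if (sum(undef) == 1) "y" else "ies")
  validObject(mle)
  mle
}
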