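---
title: "Ranking interventions in the WRKY drought-response network"
author: "wrkyBN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking interventions in the WRKY drought-response network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyBN)
```

## The model

Under drought, the plant hormone abscisic acid (ABA) induces the
transcription factors WRKY18, WRKY40 and WRKY60 in Arabidopsis. WRKY18 and
WRKY60 promote the downstream drought-response gene; WRKY40 antagonizes
them. The three factors also dimerize into homo- and heterocomplexes that
carry part of the regulation. wrkyBN encodes this pathway as an eight-node
binary Bayesian network (BN):

| node | role | parents |
|------|------|---------|
| A | WRKY18 (TF) | — |
| B | WRKY40 (TF) | — |
| C | WRKY18–40 complex | A, B |
| D | WRKY18–18 complex | A |
| E | WRKY40–40 complex | B |
| F | WRKY60 (TF) | C |
| G | WRKY60–60 complex | F |
| H | drought-response gene | D, E, G |

Every node is binary: 1 means activated/upregulated, 0 inhibited. The joint
distribution factorizes node by node given parents, so the model is fully
specified by 22 local probabilities (one per node per parent configuration).
Node identity is the letter; the biological labels are display metadata and
can be overridden in `buildWrkyNetwork()` — the complex composition of C and
D in particular is read off the pathway diagram rather than fixed by data.

The network is multiply connected (A and B reconverge on H along two
routes), which rules out Pearl-style message passing. All inference here is
instead **exact enumeration** of the 2^8 = 256 joint states, in linear
space (underflow is impossible at this size), with a fixed sorted node
order so results are bit-stable.

## Data: observed genes, synthesized complexes

Expression data exist only for the gene/TF nodes A, B, F, H. The
preprocessing chain is:

1. `readExpression()` — strict CSV/TSV parsing (non-numeric cells and
   duplicate gene ids are located errors, never coerced).
2. `normalizeExpression()` — per-gene, per-dataset. The method is a recorded
   choice (`zscore` default, `minmax`, `none`): the composite the analysis
   emulates was built from individually normalized series without a stated
   method, so no default is claimed to match the original run.
3. `binarizeExpression()` — per gene, 1 iff expression is *strictly* above
   the gene's mean (or median). Ties map to 0, deterministically; a
   constant gene binarizes to all zeros. Probe-to-node mapping is an
   explicit config table because probe ids differ across platforms.
4. `aggregateBinary()` — row-wise concatenation by column name into one
   composite; complex columns are created as explicitly missing, never
   imputed here.

No expression data can exist for the protein complexes, so their states are
**synthesized from the network dependencies** (`synthesizeAll()`): each
complex node conditions on its observed parents and children. When those
fully agree with one complex state the value is deterministic (e.g. A=1 and
H=1 forces D=1); ambiguous configurations assign the favoured value `v`
with a probability `p` drawn uniformly from {0.6, 0.7, 0.8, 0.9, 1.0}
(fresh draw per observation), else `1 - v`. The favoured value therefore
appears at rate 0.8 in the long run. Two readings of "randomly selected"
exist — one draw per row or one per run — and per-row is the default, with
`drawPerRow = FALSE` available. Assignments of the value 0 use the same
probability set symmetrically. Draws come from per-node seed streams
derived from the run seed, so synthesis order cannot change results.

`generateComposite()` closes the loop for testing: it forward-samples a
complete ground-truth dataset from a known parameter set, drops the complex
columns, and re-synthesizes them — enabling parameter-recovery and
procedure-consistency checks without any real data. The default composite
size of 116 observations mirrors the aggregated real study; the 40+40+36
split used in test fixtures is a fixture choice (the per-series counts are
not published).

What the generator does *not* emulate: platform noise, batch effects,
probe-level ambiguity, or any dependence of the assignment probabilities on
biology. Passing tests show the pipeline is internally consistent and
recovers parameters from data that obey the model, not that the model fits
any particular microarray series.

## Parameter estimation

With binary nodes, n observations of a parent configuration containing k
activations give a Binomial likelihood. Two estimators are provided:

* **Bayesian** (`bayesianEstimate()`): conjugate Beta prior, default
  Beta(1, 1) (uniform). Posterior Beta(α + k, β + n − k); the point
  estimate is the posterior mean (k + 1)/(n + 2) under the default prior —
  strictly inside (0, 1) for any finite data, so unobserved configurations
  get a proper estimate (0.5 under the uniform prior) rather than 0.
  Per-entry informative priors can be supplied as a data frame.
* **MLE** (`mleEstimate()`): k/n. It can reach the boundary and is
  *undefined* when a configuration never occurs; such entries are flagged
  and refused by inference rather than silently zeroed. The pipeline
  substitutes the Bayesian estimate and logs it (`fillUndefined()`).

Estimation is closed-form and batch; the point estimate is the posterior
mean, not the mode. As data grow the two estimators converge, and
`compareEstimates()` tabulates them side by side in `P(C1 |A1,B0)`-style
notation.

## Utility-based intervention ranking

To find the best single-node intervention for upregulating H, the BN
becomes a decision network: acting on a node makes it deterministic. We use
do-semantics (`intervene()`): the node's incoming edges are severed and its
distribution replaced by a point mass. For the root-node actions of the
worked example this is indistinguishable from conditioning; for non-root
nodes do-semantics matches the "becomes a deterministic node" reading and
is the standard causal choice.

The expected utility of action `a` is `EU(a) = Σ_i P(O_i | a) U(O_i)`, where
the outcomes `O_i` are the configurations of the utility scope. The scope is
the target's parent set (G, D, E) — not H itself, which is marginalized
out. Because H is a leaf, its own conditional probabilities cancel from
every outcome distribution; the bundled reference parameter set
(`wrkyReferenceParameters()`) fills them with 0.5 and marks them inert. The
default utility table (`wrkyUtilityTable()`) scores G=1, D=1, E=0 best
(100) and G=0, D=0, E=1 worst (0), with intermediates at 10/50. Utilities
are dimensionless reals; only differences matter (EU is exactly equivariant
under adding a constant), and no normalization is applied.

`rankInterventions()` evaluates both actions for every candidate node
(A–G), sorts by EU with a deterministic (node, action) tie-break, and also
reports the per-node maximum over the two actions. With the reference
probabilities, activating WRKY18 (A) ranks first, activating the WRKY60–60
complex (G) is the second-best activation, and the antagonists WRKY40 (B)
and WRKY40–40 (E) score higher for inhibition than activation:

```{r ranking}
net <- buildWrkyNetwork()
rk <- rankInterventions(net, wrkyReferenceParameters("bayes"),
                        wrkyUtilityTable())
head(rk)
```

## Numerical and design choices

* **Enumeration, not sampling.** All probabilities and EUs are exact sums
  over 256 states; test tolerances (1e-10 against an independent
  brute-force oracle) reflect floating-point accumulation only.
* **Degenerate inputs.** Zero-probability evidence raises an explicit
  error rather than returning 0/0; intervening on the decision target is an
  error; synthesis refuses to overwrite an existing complex column; missing
  values must be synthesized before estimation.
* **Determinism.** A run is reproducible from (config, seed). Forward
  sampling and synthesis restore the caller's RNG state; synthesis uses
  per-node streams keyed by the run seed.
* **Problem sizes in tests.** Oracle-equivalence checks use 100 random
  parameter sets; parameter recovery uses 20 000 forward-sampled
  observations (each parent configuration is then populated well enough
  that both estimators sit within 3 binomial standard errors of truth and
  within 0.01 of each other); synthesis-rate checks use 10 000 rows. These
  sizes make the stochastic checks sharp while keeping the default test run
  quick.

## Limitations

* Structure is fixed by prior biological knowledge; no structure learning
  is attempted (deliberately, given the small data).
* Single-node interventions only; multi-node actions are out of scope.
* Only point estimates feed the decision stage; posterior uncertainty in
  the parameters is not propagated into EU.
* The utility values encode a relative preference ordering, not measured
  payoffs; rankings are meaningful, the absolute EU scale is not.
* Reproducing the exact published composite dataset requires the original
  GEO series and their (unstated) normalization; the pipeline implements
  the procedure, not that byte-exact dataset.
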