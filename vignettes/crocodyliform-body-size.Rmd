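---
title: "Scaffold-constrained parsimony and phylogenetic body-size estimation"
author: "crocsize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold-constrained parsimony and phylogenetic body-size estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crocsize)
```

## The analysis chain

`crocsize` implements the computational chain behind morphology-based
macroevolutionary studies of crocodyliforms: a discrete taxon-by-character
matrix is scored and searched under maximum parsimony with a molecular
scaffold constraining the extant species; the strict consensus of the best
trees is time-calibrated from tip ages with the minimum-branch-length (mbl)
rule; total body length (TL) of fossil tips is imputed from head width (HW)
through a Bayesian log-log allometry with Brownian-motion phylogenetic
residuals; and the resulting sizes, discretised into bins, are pushed back
through the tree by parsimony ancestral-state reconstruction, alongside a
binary osmoregulation character.

This vignette records the model assumptions, the tunable parameters, the
numerical conventions, and what the synthetic-data generator does and does
not emulate.

## Parsimony scoring and reconstruction

Characters are discrete with integer states. Unordered characters cost 1
per change (Fitch); characters flagged as ordered -- morphoclines -- cost
`|i - j|` along the integer cline (Wagner). Both are special cases of a
step matrix, so scoring uses the Sankoff dynamic programme throughout:

* tips enter with cost 0 on every member of their ambiguity set
  (polymorphic or uncertain scores such as `[01]`) and infinity elsewhere;
* missing (`?`) and inapplicable (`-`) scores cost 0 on every state and
  therefore contribute nothing on any topology -- inapplicable scores are
  deliberately collapsed into missing, the standard practice when no
  reductive coding is specified;
* polytomies are scored as hard polytomies over the given node degrees;
* for ordered characters the ancestral state universe is the full integer
  range between the observed minimum and maximum (intermediate unobserved
  states are legal on a morphocline); for unordered characters it is the
  observed state set.

`mpr_states()` returns, for every node, the complete set of
most-parsimonious reconstructions -- every state the node takes in at least
one minimum-cost labeling -- with no ACCTRAN/DELTRAN resolution. For a tip
scored as missing the set contains the states it can take at zero cost,
i.e. the states its parent takes in some minimum labeling.
`enumerate_parsimony()` provides an independent brute-force reference
(exhaustive enumeration of internal labelings) used throughout the tests;
both routes agree exactly on hundreds of randomized instances with mixed
ordered/unordered characters, missing data and polymorphism.

## Tree search under a molecular scaffold

The backbone constraint fixes extant relationships from molecular
topologies while fossils float: a tree is admissible when its restriction
to the constrained taxa contains every clade of the backbone (it may be
more resolved). The search is deliberately a simple, reproducible
desk-scale heuristic, not a re-implementation of the "new technology"
machinery used on very large empirical matrices: random-addition starting
trees (each taxon placed at its best admissible position), then NNI or SPR
hill climbing accepting only admissible neighbours, pooling all distinct
equally-best trees across replicates. Determinism is guaranteed by the
mandatory seed; ties are broken by canonical (lexicographic) newick order.
Trees are rooted on a designated outgroup -- by default the first taxon of
the matrix, following the common convention of listing the outgroup first.
On small problems (up to 7-8 taxa) the search is validated against
exhaustive enumeration of all topologies; with 10 addition replicates it
recovers the global optimum in effectively all random 7-taxon instances.

## Minimum-branch-length calibration

Tip ages come from a `taxon, fad, lad` table (Ma). The default calibrating
age is the FAD (first appearance), the usual choice when calibrating first
appearances of fossil taxa; LAD and midpoint are available. Node ages are
the *pointwise minimal* ages satisfying (i) a node is at least as old as
its oldest descendant tip and (ii) every branch lasts at least
`min_branch` Myr. A single postorder recursion,
`age(node) = max over children (age(child) + min_branch)`, realises both
constraints exactly, is deterministic and idempotent, and is verified
against an order-free constraint-propagation fixpoint oracle. The
analysis default is `min_branch = 5` Myr (display trees in this literature
typically use 1 Myr). Polytomies are calibrated as-is; downstream
covariance matrices are well defined on polytomous trees, so no arbitrary
resolution is introduced. Floating-point age comparisons use a 1e-9
tolerance.

## Allometry and Bayesian body-length imputation

The regression is `log10(TL_cm) = a + b log10(HW_cm)` over extant taxa,
with specimens averaged per taxon on the log scale (multiplicative
measurement error is symmetric there). Base-10 logarithms are the
convention of the body-size estimation literature this mirrors; the base
only rescales coefficients. Residuals carry the phylogenetic covariance
`sigma2 * C(lambda)`, where `C` is the Brownian-motion variance-covariance
of the calibrated tree scaled to unit variance at the deepest tip, and
Pagel's lambda multiplies the off-diagonal entries.

`predict_tl()` samples a conjugate Gibbs chain: coefficients from their
Gaussian conditional (improper flat prior), residual variance from its
inverse-gamma conditional (IG(0.001, 0.001) prior), and per draw each
fossil's log10 TL from the Brownian conditional given the extant
residuals -- kriging mean `x_f b + C_fo C_oo^-1 (y - X_o b)` and the
matching conditional variance. Draws are back-transformed to cm and
summarised by mean and 2.5/97.5 percentiles, so predictions are positive
and quantile-ordered by construction. Defaults are 10,000 iterations,
1,000 burn-in, thinning 10, and a mandatory seed.

Lambda is *plug-in*: held fixed during the MCMC, mirroring the published
workflow in which an externally computed phylogenetic signal value is
supplied to the Bayesian predictor. When not supplied it is estimated by
profiling the restricted likelihood of the GLS regression itself (REML
keeps the estimate from absorbing coefficient uncertainty; estimating
lambda from OLS residuals biases it downward). The trait-only estimator
`estimate_lambda()` (ML, bounded in `[0, 1]`, endpoints checked) matches a
1e-4 grid search and, on strong-signal simulations, phytools-style
estimates. Since lambda is plugged in rather than sampled, posterior
intervals are very slightly narrower than fully Bayesian ones; in the
package's own calibration experiments (200 replicates, about 20 extant
taxa) 95% intervals for the slope and for withheld fossil lengths cover
the truth at 90-95%.

## Size bins, ancestral states and reduction percentages

Size categories follow the extant-calibrated bounds: small (0, 150] cm,
medium (150, 400] cm, large (400, 700] cm, gigantic above 700 cm. Bounds
are upper-inclusive -- "about 1.5 m and lower" makes 150 cm small -- and
applied uniformly. Fine bins for ancestral-state plotting default to 50-cm
classes (configurable), the width implied by published bands such as
150-200 cm and 200-250 cm; mean TL estimates per taxon are the plotted
quantity. Bin reconstruction uses ordered (Wagner) costs between adjacent
bins; osmoregulation -- coded saltwater-tolerant / freshwater-only /
unknown from salt-gland, isotopic and occurrence proxies -- uses Fitch
costs with unknowns as missing. Published "equal branch length" plotting
is display-only: parsimony reconstruction is branch-length-free, so no
length weighting exists to implement. Codings are read from user-editable
tables, not hard-coded.

The reduction band between an ancestral bin `[la, ua]` and a descendant
bin `[ld, ud]` is reported relative to the ancestral upper bound:
`min = (1 - ud/ua) * 100`, `max = (1 - ld/ua) * 100`. This is the one
convention that reproduces both published figures (20% minimum for
200-250 cm to 150-200 cm, reaching 40% when shrinkage passes below
150 cm); it is logged as a convention, not a claim about the original
unstated formula. A descendant bin above its ancestor clamps the minimum
at 0 with a note.

## What the generator emulates -- and what it does not

`simulate_tree()` grows a constant-rate birth-death tree forward in time
(defaults: 0.06/0.03 per lineage per Myr, plausible for crocodyliform
clades at Myr scale), stopping when the requested number of tips exists;
extinct tips get point FAD = LAD ages, survivors age 0.
`simulate_matrix()` evolves Mk-type characters (default 3 states, a fifth
ordered -- ordered ones as adjacent-step chains, matching the Wagner cost
model), with a uniform missing mask (default 25%, of the order seen in
morphological matrices). `simulate_allometry()` draws HW log-uniform over
10-60 cm (the extant crocodylian range), with truth slope 1 and intercept
0.9 (TL roughly 8 x HW, near-isometry), residual sigma2 0.01 and lambda
0.9, and withholds TL for a configurable fossil fraction. Streams are
per-component, derived from the master seed.

The generator does not emulate character correlations of real
morphological matrices, non-uniform missingness (fossils are missing in
blocks, not at random), rate heterogeneity, or body-proportion divergence
of taxa far outside the extant sample. Passing tests therefore demonstrate
correctness of the machinery and calibration under the stated model, not
robustness to model violation in empirical data -- the same caveat that
applies to the published method chain itself.

## Problem sizes and test design

Validation uses instance sizes where independent exact references exist:
parsimony against exhaustive labeling enumeration (up to 8 taxa, 6
characters, 4 states; 200 instances), search against all 945 seven-taxon
topologies (50 matrices), calibration against a fixpoint oracle (100
ten-tip trees), and interval calibration with 200 simulation replicates of
about 20 extant taxa with 2,000-iteration chains. These sizes give stable
Monte-Carlo estimates while keeping the whole suite fast; all are
configurable upward.

## Known limitations

* The search is desk-scale; empirical matrices with > 100 taxa need the
  dedicated parsimony programs this package deliberately does not
  re-implement, and most-parsimonious-tree *counts* are not comparable
  across programs (they depend on branch-collapsing rules).
* NEXUS support is a read-only subset (MATRIX block plus `ord:` typesets);
  TNT support covers `xread` and `ccode`/`cc` ordering directives, with
  other commands ignored with a warning. Interleaved blocks are supported
  only when each block line is attributable by row-fill order.
* Lambda is plug-in rather than jointly sampled; alternative covariances
  (OU, early burst) and multi-proxy regressions are out of scope.
* `run_pipeline()` is the orchestration surface; there is no shell
  executable -- the exported functions are the interface.
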