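---
title: "Methods: propagation-based pathway disruption analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propagation-based pathway disruption analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathprop)
```

## The model and its assumptions

`pathprop` quantifies how strongly each biological pathway is disrupted by
somatic copy-number alterations (CNAs) in each of several cancer types.
The core assumption is that amplification or deletion of a gene perturbs
not only that gene but also its interaction partners, so disruption should
be measured on a signal that has been diffused over the protein–protein
interaction (PPI) network rather than on the raw altered-gene list.

Per cancer type, the input is a gene-level CNA summary (GISTIC-style):
seed genes inside recurrently altered regions, each with an average log2
ratio across patients and usually a q-value. The initial activity vector
`g` places each seed gene's average |log2 ratio| on the network (zero
elsewhere). Propagation solves

$$\tilde g = (1-\alpha)\,(I - \alpha \bar G)^{-1} g,
\qquad \bar G = D^{-1/2} G D^{-1/2},$$

the unique minimizer of a quadratic criterion that penalizes differences
between connected genes while staying faithful to `g`. `I - αḠ` is
strictly diagonally dominant-like for `α ∈ (0,1)` (the spectral radius of
`Ḡ` is at most 1), so the solution exists, is unique, and is reached by
the fixed-point iteration `g̃_t = (1-α) g + α Ḡ g̃_{t-1}` from any start.
A note on naming: the operator above is the symmetric-normalized
*adjacency*; some presentations of this family of methods label it a graph
Laplacian, but the closed form and the update rule both require the
normalized adjacency, which is what we implement.

Pathway activity in one cancer is the arithmetic mean of propagated
scores over the pathway's member genes; the pathway × cancer matrix of
these scores is the object everything downstream consumes.

## Parameters that matter

* **`alpha` (unitless, default 0.5).** Balances network smoothness against
  fidelity to the seed scores. At `α → 0` the output equals the input; at
  large `α` signal diffuses broadly. 0.5 is the conventional midpoint used
  by this method family and our default.
* **Score mode (default `magnitude`).** Deletions carry negative average
  log2 ratios. The default takes absolute values so amplifications and
  deletions both contribute positive disruption mass — signed scores would
  let a pathway hit by both cancel to zero, and mixed amp/del pathways are
  an observed, biologically real phenomenon. `signed` mode is provided for
  sensitivity analysis.
* **Amp+del conflicts.** A gene carrying both record types takes the record
  with the larger |average| (tie toward amp), mirroring the
  "more significant q-value" rule used for q-based rankings.
* **`min_members` (default 3).** Pathways with fewer than 3 in-network
  members are flagged and excluded from ranking, so single-gene "pathways"
  cannot dominate.
* **Denominator choice.** Pathway scores average over members *present in
  the network*; counting absent members as zeros (available via
  `all_members = TRUE`) would penalize pathways for interactome coverage
  gaps, which is database incompleteness, not biology.
* **Permutations (`n_permutations`, default 10,000).** The null shuffles
  initial gene scores (with re-propagation) and replaces member sets with
  size-matched random sets; `mode` selects either ingredient alone.
  Empirical p-values use the +1 correction, `p = (1 + #{x ≥ s})/(B + 1)`.
* **FDR cutoffs.** BH adjustment is applied within each
  (cancer, collection) family; cutoffs are per collection label
  (0.005 for Biocarta-like curated sets, 0.10 by default elsewhere).
* **Selection.** Per cancer: significant *and* top 20% by activity.
  Commonly disrupted: significant and top 10% in ≥ 10 cancer types
  (top 5% recommended for large subnetwork-module collections).
  Cancer-specific: qualifying in ≤ 2 cancer types (configurable; no
  canonical value exists for this bound, 2 keeps "specific" strict).

## Numerical choices

* The closed form is computed by a sparse linear solve of
  `(I - αḠ) x = (1-α) g`, never by explicit inversion.
* The iterative solver starts from `g̃_0 = g` (any start converges; the
  input is the natural warm start) and stops when the max-norm change
  drops below `1e-9`, strict enough that closed-form/iterative agreement
  holds at `1e-8` in tests.
* Degree-zero nodes get zero rows in `Ḡ` (their propagated score is
  exactly `(1-α) g_i`), avoiding division by zero in `D^{-1/2}`.
* Node order is lexicographic and all rank ties break by pathway name, so
  every output file is byte-stable under reruns.
* Hierarchical clustering is complete-linkage agglomeration on
  `1 - Pearson` distances (the conventional metric of the desktop tool
  this analysis style comes from; Euclidean available). Ties in the
  agglomeration merge the lexicographically smallest cluster pair, and the
  within-merge leaf order is label-canonical, so trees do not depend on
  input row order. Z-scores use the sample (n−1) standard deviation.
* Zero q-values are clamped to the smallest positive q in the table
  before `-log10` ranking.
* In the disruption-neighborhood view, interactors are ranked by their
  best (min of amp/del) q-value; ties at the boundary rank are all
  included. The default rank cutoff of 500 follows the method's
  convention for genome-wide (~19k gene) rankings.

## The permutation null and its speed knob

The faithful null (`mode = "both"`) re-propagates every permuted score
vector, which costs one sparse solve per permutation; solves are batched
500 at a time. `mode = "membership"` keeps the observed propagated vector
fixed and randomizes member sets only — a fast approximation appropriate
for tests, exploration, and large simulation studies.

`share_nulls_by_size = TRUE` additionally draws, per permutation, a single
partial random permutation of the gene universe and reads every pathway
size's null score off its running mean. Each pathway's marginal null is
exactly a uniform random same-size set, so individual p-values are
unbiased, but p-values of different pathways become positively correlated
within a permutation. We use it in the heavy recovery/determinism
benchmarks; the calibration study below uses the unshared i.i.d. path, and
calibration claims should always be made with sharing off.

At desk-scale permutation counts the BH floor matters: with `B`
permutations the smallest achievable p is `1/(B+1)`, and a lone true
positive among `P` pathways can at best reach `q = P/(B+1)`. Benchmarks
that expect a single planted pathway to clear `q ≤ 0.10` therefore need
`B ≥ 10·P`; the acceptance suite uses `B = 3999` for 200 pathways. This is
arithmetic, not tuning — the production default of 10,000 shuffles makes
the floor irrelevant.

## What the synthetic generator emulates — and what it does not

`scenario_spec()` defaults state the benchmark world once: 2,000 genes
with mean degree 16 (matching the density of the ~9.7k-protein,
~76k-edge reference interactome this method family targets), 16 cancer
types, 200 pathways of 10–40 genes, 5% of genes altered per cancer with
mean |log2 ratio| 1.0 (one copy gained or lost on average; magnitudes
lognormal with sdlog 0.3), q-values log-uniform between 1e-8 and ~0.03,
10% of records flagged arm-level. The `direct` scenario alters each
planted-pathway member with probability 0.5 — the "half the members
altered" textbook picture of an enriched pathway — in 12 of 16 cancers;
`neighbor_only` applies the same rule to the members' direct interactors
instead and guarantees zero altered members, the configuration that
overrepresentation tests cannot see at all; `null` plants nothing. In the
neighbor-only scenario the altered interactor zone is additionally kept
out of every other gene set's membership: the scenario being emulated is
precisely an alteration signal carried by *unannotated* genes (in real
data the large majority of significantly altered genes appear in no
pathway database), and if the generator instead scattered those genes
into other pathways as direct members, it would be simulating a different
— annotated — world.
Erdős–Rényi is the default topology; planted-partition (community) and
preferential-attachment generators are provided because pathway genes
cluster in real interactomes and degree distributions are heavy-tailed.

A green test on this world establishes that the statistical machinery
does what it claims under stated noise — it does not establish biological
validity. The generator has no chromosome geometry (alterations are
segment-free, so no spatially correlated passenger genes), no shared
driver architecture between cancer types beyond the planted pathway, no
annotation bias, and no correlation between degree and alteration
propensity, all of which shape real data.

## Design decisions taken where the design was open

* Whether re-propagation follows each score shuffle in the published
  permutation scheme is ambiguous; `mode = "both"` re-propagates
  (faithful), `membership` does not (fast), and neither is asserted to be
  the historical procedure.
* Seed genes absent from the network are dropped (they cannot propagate)
  and counted in a warning, making interactome coverage loss visible.
* The enrichment-baseline universe is the measured gene population (the
  significance table), with the full network as a config alternative.
* The command line is a single YAML-config runner with flag overrides
  rather than a subcommand multiplexer: every pipeline stage is an
  exported, documented R function, which is the idiomatic R surface for
  composing partial runs.

## Known limitations

* Identifier handling is uppercase-and-trim only; users must pre-map
  aliases to a common gene symbol namespace.
* Interactions are binary; weight columns are ignored with a warning.
* Amplification and deletion are not distinguished in the default score
  (see above); interpretation of *which* alteration type drives a called
  pathway requires going back to the seed tables.
* No parametric p-values are offered; at small `B` the discreteness of
  empirical p-values limits attainable q-values (see the BH-floor note).
* The co-disruption correlation is computed across cancer types (n = 16
  in the reference design), so individual correlation estimates are noisy
  and should be read as exploratory structure, not tested associations.
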