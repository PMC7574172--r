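---
title: "Methods: predicting a functional interactome and interpreting gene sets with funclink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting a functional interactome and interpreting gene sets with funclink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funclink)
```

## The problem

Experimentally confirmed protein interactions cover only a small slice of
any organism's interactome, while transcriptome experiments routinely
produce sets of differentially expressed genes (SDEGs) that no curated
annotation describes well. funclink implements a two-part answer:

1. **Predict a functional gene association network** by integrating several
   categories of indirect evidence (co-expression, shared annotation,
   subcellular co-localization, domain interaction, phylogenetic profiles,
   interologs) with a soft-margin Gaussian-kernel SVM trained on
   high-quality known interactions.
2. **Interpret SDEGs against that network** with gene set linkage analysis
   (GSLA): an SDEG is linked to an annotated gene set when the density of
   network edges between the two sets is high (Q1) *and* higher than
   expected from degree-preserving randomizations of the network (Q2).

Everything runs on plain tabular inputs (TSV edge lists, GMT gene sets,
dated annotation tables), and a synthetic world generator provides a
fully known ground truth for testing and calibration.

## Evidence features and screening

Six feature categories are implemented (17 features in total), each behind
the same interface: a raw evidence table plus a pair list in, a tibble of
pair-indexed feature columns out.

| category | features | missing when |
|---|---|---|
| co-expression | Pearson correlation; mutual rank $1/\sqrt{r_a(b)\,r_b(a)}$ | gene absent or zero-variance |
| shared annotation | shared-term count; Jaccard; $-\log_{10}$ of rarest shared term frequency | gene unannotated |
| co-localization | shared-compartment count; Jaccard; best min-confidence; indicator | gene unlocalized |
| domain interaction | scored domain-pair count; max; sum; mean | gene domainless |
| phylogenetic profile | Hamming similarity; profile correlation; presence Jaccard | gene without profile |
| interolog | any-species ortholog-interaction indicator | never (no ortholog scores 0) |

Pairs for which evidence is genuinely absent carry `NA` and a
missing-value mask; absence of interolog evidence scores 0, because a
searched-but-empty ortholog catalogue is evidence of absence rather than
missingness.

Each feature is screened by its ROC AUC against labeled pairs
(Mann–Whitney form, ties credited 0.5). A feature is retained only when
its AUC is **strictly greater than 0.6**. The 17 implemented features are a
representative per-category subset behind a uniform interface; the
screening and SVM stages are formula-agnostic, so additional
characterizations can be added without touching them.

## Training design

* **Positives**: known interactions filtered for quality — kept only if
  reported by at least two independent studies *and* not supported solely
  by high-throughput experiments. "High-throughput only" is taken as an
  input flag on each record, since no operational throughput definition is
  universal.
* **Negatives**: random gene pairs excluding positives at a **1:100**
  positive:negative ratio. The imbalance is carried by the data itself (no
  class weights): the prior that a random pair interacts is small, and the
  trained decision threshold inherits it.
* **Model**: soft-margin SVM with Gaussian kernel
  $K(x,y)=\exp(-\lVert x-y\rVert^2/2\sigma^2)$ (libSVM via e1071, which
  parameterizes $\gamma = 1/2\sigma^2$). Selected features are
  median-imputed and min–max scaled to $[0,1]$ using labeled-pair bounds;
  both sets of parameters are stored in the model artifact because RBF
  kernels are scale-sensitive and prediction must be self-contained.
* **Model selection**: $(\sigma, C)$ grid search maximizing the harmonic
  mean of sensitivity and specificity under stratified 5-fold
  cross-validation. Confusion counts are **pooled** across folds rather
  than averaged — per-fold rates are unstable when a fold holds only a
  handful of positives. Ties break toward smaller $C$, then smaller
  $\sigma$, making the search invariant to grid ordering. The default
  $\sigma$ grid is $2^{-4}\ldots2^{4}$ times the median pairwise distance
  of the preprocessed data; the default $C$ grid is $2^{-2}\ldots2^{6}$.
* **Final fit**: all labeled data at the selected hyperparameters; the
  decision threshold is 0 (sign of the decision value), with no
  probability calibration. Predicted edge weights are the logistic
  transform of the decision value — a monotone squashing into $(0,1)$,
  not a calibrated probability.

## Interactome size estimation

With validated sensitivity and specificity, the number of predicted
associations satisfies

$$N_{\text{interactome}}\cdot\text{sens} +
  (N_{\text{all pairs}} - N_{\text{interactome}})\cdot(1-\text{spec})
  = N_{\text{predict}},$$

which `estimate_interactome_size()` solves for
$N_{\text{interactome}}$, requiring $\text{sens} > 1-\text{spec}$ (below
that the equation is non-identifiable) and clipping to
$[0, N_{\text{all pairs}}]$ with a warning. $N_{\text{all pairs}}$ is
always an explicit input derived from a stated gene universe — it is never
inferred from edge files. The sensitivity entering the equation follows a
conservative policy: the default takes the minimum of the training-stage
and validation-stage estimates. Derived quantities
(`expected_ppi()`, `coverage_of_interactome()`) are computed from
**unrounded** intermediates; reporting chains that round the size estimate
before multiplying will disagree with the fraction computed from the
rounded count by a percent or two, which is expected and documented
rather than reconciled.

## Assessing a network by function prediction

A good functional network groups functionally related genes, so its
neighbourhoods should predict annotations that were not yet known when the
network was built. The assessment is a strict time split: annotations
dated up to the cutoff are "known", strictly later ones are "new". For a
gene with $n$ neighbours in an $N$-gene universe (the gene itself
excluded) of which $K$ carry a term, the prediction statistic is the exact
hypergeometric upper tail of observing $\ge k$ carriers among the
neighbours. A gene's own annotations never enter its neighbour evidence,
and only (gene, term) pairs *not* already known are scored. The enrichment
engine is implemented in-package as an exact hypergeometric by design —
this keeps the statistic fully specified rather than delegating to an
external annotation service.

Precision at a cutoff is the fraction of reported pairs present anywhere
in the full corpus (known ∪ new); recall is the fraction of new
annotations recovered. The default cutoff grid is 19 log-spaced points in
$[10^{-10}, 0.1]$. No multiple-testing correction is applied along the
curve (the curve *is* the sweep over raw cutoffs); Benjamini–Hochberg
q-values are available for single-cutoff reporting.

## GSLA: the Q1 and Q2 tests

For an SDEG $A$ and an annotated set $B$, overlap genes are removed from
the annotation side ($B' = B \setminus A$) and the density is
$|E(A,B')|/(|A||B'|)$. The overlap removal is a deliberate choice: it
prevents a set from associating with itself through shared members and
keeps the statistic defined for overlapping sets. Edge weights are
ignored — density is a count.

* **Q1** reports a set when density strictly exceeds 0.01 (default).
* **Q2** compares the observed density against networks rewired by double
  edge swaps (igraph's degree-preserving rewiring; swaps creating
  self-loops or duplicate edges are rejected), each permutation rewired
  fresh from the original network with $10|E|$ swap attempts. The p-value
  uses the add-one estimator $(1+\#\{d_{\text{null}}\ge
  d_{\text{obs}}\})/(1+n_{\text{perm}})$, so it is never 0 and its floor
  is $1/(n_{\text{perm}}+1)$; 1000 permutations support the default
  $p < 0.001$ cutoff. A hub-rich query can pass Q1 easily while failing
  Q2, which is exactly the confounding the permutation controls:
  rewiring preserves every gene's neighbour count, so density driven by
  degree alone is reproduced in the null.

Candidates are ranked by p-value then density; BH q-values across the
collection are emitted as an extra column but the default report uses raw
p-values with the fixed cutoffs. Queries of 50–200 genes are recommended
(outside that range a warning, not an error). One rewired network per
permutation is shared across all candidate sets, which keeps cost
independent of collection size without affecting any single set's null.

## The synthetic world

`make_world()` plants a stochastic block model: genes are assigned to
modules (near-equal sizes), intra-module pairs carry edge probability
`p_in` = 0.3 and inter-module pairs `p_out` = 0.005 (defaults: 500 genes,
10 modules). An SBM was chosen over preferential attachment because
module structure is precisely what GSLA and the assessment stage must
detect; an optional hub overlay exists for hub-confounding experiments.
Evidence tables are then generated so that the *primary* feature of each
category discriminates planted edges from non-edges at a configured AUC
target (default 0.75 per category):

* Module-driven channels (expression factor correlation, module terms,
  module compartments, module domain pairs, module profiles) act through
  the latent "same module" indicator. The effect size of each channel is
  solved numerically (closed-form count distributions, `uniroot`) so that
  the theoretical Mann–Whitney AUC — mixing intra-module fractions among
  edges ($h_e$) and non-edges ($h_n$) realized in the drawn network —
  hits the target. The co-localization calibration additionally conditions
  on both genes being localized, since feature AUCs exclude missing pairs
  pairwise.
* The interolog channel is pair-driven: foreign interactions are
  transferred onto true edges at a calibrated rate over a background rate.
* Each category also emits a **noise** table built by permuting gene
  labels of signal-shaped evidence — marginals are preserved exactly while
  any correlation with the planted edges is destroyed (expected AUC 0.5).

Calibration is approximate where the theory is approximate: the
co-expression channel uses the Fisher z approximation and typically
realizes an AUC a few points above target at the default sample size;
count channels land on target. Realized AUCs across seeds span roughly
0.74–0.80 for a 0.75 target, which the screening margin (cutoff 0.6)
absorbs comfortably.

Because all evidence channels share the module structure, the generative
model has a tractable exact form: given the intra-module indicator, the
category channels are independent. `world_bayes_score()` exploits this to
compute the exact log-likelihood ratio of the primary features under the
generative model — the Bayes-optimal ranking score — against which the
trained SVM is compared at matched specificity. What the world does *not*
emulate: scale-free degree structure (unless the hub overlay is enabled),
ontology structure among terms, inter-module functional coupling, or
realistic worm gene counts; passing tests demonstrate correctness of the
machinery under a known truth, not performance on real data.

## Numerical and design choices

* Unordered pairs are stored canonically (lexicographically smaller gene
  first); all dedup and set algebra runs on that canonical form.
* Dates are ISO-8601; "new" annotations are strictly after the cutoff.
* Unmapped and ambiguous IDs are excluded and reported, never guessed.
* A duplicated edge keeps `known` provenance and the larger weight.
* `sample_negatives()` uses rejection sampling with canonical pair
  encoding, switching to exact complement enumeration when the request
  exceeds half the available pairs (so small universes are sampled
  without replacement correctly).
* Every stochastic step takes an explicit seed; the synthetic world is
  byte-reproducible from (config, seed).

Two calibration subtleties deserve a note because they shape the test
suite. First, Monte-Carlo exactness of Q2 is checked on 6-node fixtures
against exhaustive enumeration of all degree-matched simple graphs; those
checks use 50 swap attempts per edge rather than the default 10 so that
sampler mixing on a tiny state space does not confound the comparison of
Monte-Carlo error against binomial theory. Second, uniformity of Q2
p-values under the null is checked on a beta-model random graph (edge
odds factorizing over nodes), because such a graph conditioned on its
degree sequence is exactly uniform — the permutation null holds by
construction. On a strongly modular network the null is false even for
uniformly drawn SDEGs: random sets overlap modules, the real network's
inter-set density is genuinely more variable than its rewirings, and Q2
correctly flags that structure. That behaviour is the method working,
not a calibration defect, and the hub fixture above probes its
complement.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the full pipeline at
deliberately modest scales chosen as representative working points:
500-gene worlds for screening and SVM recovery (100 training positives at
1:100, 200–300 validation positives), a 300-gene world for the end-to-end
run and assessment curves, 200 replicates × 200 permutations for the Q2
calibration check, and 999–2000 permutations where a p-value floor below
the reporting cutoff is needed.

## Known limitations

* The representative feature set (17 formulas) does not reproduce every
  domain-interaction variant used in large evidence compilations.
* No ontology-aware semantic similarity; terms are opaque identifiers.
* The Q1 threshold form is the fixed default; an empirical variant
  (percentile against random same-size sets) is a natural extension point.
* Decision values are not calibrated probabilities; edge weights order
  predictions but should not be read as interaction probabilities.
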