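---
title: "Inferring causal transcription factors from DEG lists with multi-layer downstream models"
author: "causalTF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring causal transcription factors from DEG lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalTF)
```

## The problem

A perturbation experiment (a TF knockout, an overexpression, a physiological
transition) yields a list of differentially expressed genes (DEGs). The
inverse problem — which regulator caused these changes — is harder than the
forward one, because a TF's direct binding targets overlap poorly with the
genes its perturbation actually changes. Two mechanisms break the direct
link: regulation cascades (the TF changes the expression of other TFs,
whose targets then respond) and post-translational modification (PTM — the
TF, acting for example as a kinase, changes another TF's *activity* with no
mRNA trace of its own). `causalTF` implements a TF-centered downstream
gene-set enrichment analysis that models both.

## The six downstream models

For each focal TF A the package constructs six nested downstream gene sets
from two edge types: transcription edges (TF → target gene, optionally
carrying a log-likelihood confidence score) and modification edges
(protein → protein, subkind kinase, phosphatase or modulator). Mediator
roles are named B, C, D, E, X, F:

* **I — simple direct.** A's transcription targets.
* **II — PTM-mediated direct.** I plus the targets of every TF B that A
  modifies through a kinase/phosphatase edge.
* **III — two-layer cascade.** II plus the targets of TFs C coded by A's
  targets and of TFs D coded by B's targets.
* **IV — PTM-mediated two-layer cascade.** II plus the targets of TFs E
  that are modified (modulator edge) by a protein X coded by one of A's
  targets.
* **V — hybrid two-layer cascade.** III ∪ IV.
* **VI — three-layer cascade.** V plus the targets of TFs F coded by C's
  targets.

Model VI cannot be extended further because the paths A–C–F, A–X–E and
A–B–D all already have TF-to-TF length 2, the bound beyond which the
overlap signal of the truly perturbed TF is known to wash out. An
additional PTM layer on top of Model II (targets of TFs modified by B) is
deliberately not built: it recruits only upstream kinases and, for TFs,
adds nothing beyond Model II.

Traversal rules that the definitions leave open, fixed here once:

* Mediators reached only through modification edges (roles B, E)
  contribute their targets but are not themselves downstream genes;
  mediators reached by transcription (C, D, F, and the modulator X) are
  already members as direct targets. This choice is what reproduces the
  toy network's six sets exactly (`toyNetwork()`).
* Roles B, C, D, E, F must be in the TF roster; X may be any protein coded
  by a target of A.
* Self-edges are kept in storage but never recruit a mediator, and within
  one path every role is filled by a distinct protein — both rules prevent
  degenerate cycles from inflating the sets.
* Role D is recruited only along A–B–D, and F only along A–C–F: the
  explicit path list is the specification of the models, so e.g. TFs coded
  by targets of E do not spawn a further layer.
* Genes and the proteins they code for are distinct identifier spaces tied
  by an optional `geneProduct` map; when the map is empty an identifier
  serves as both (the yeast-ORF convention used by the simulator).

`allDownstreamSets()` guarantees the nesting invariants T_I ⊆ T_II ⊆
T_III, T_II ⊆ T_IV, T_V = T_III ∪ T_IV ⊆ T_VI by construction, and the
test suite checks every constructed instance against an independent
brute-force path enumerator.

## Scoring, acceptability, ranking

With DEG set D (n genes) in a universe of N genes, a model set of size K
overlapping D in k genes is scored by the upper-tail hypergeometric
probability P(X ≥ k); k = 0 gives p = 1. The universe matters: it is taken
from the experiment's measured genes when available, else from the
network's transcribed genes — the background should be whatever could have
been called a DEG.

Because richer models can also hand spurious significance to unperturbed
TFs, each model's candidate-wide p-value distribution is compared with
Model I's by an unpaired two-sample Wilcoxon rank-sum test
(`stats::wilcox.test`: exact for small untied samples, normal
approximation with tie correction otherwise; completely tied samples are
treated as uninformative, p = 1). A model with test p ≤ α (default 0.005)
is unacceptable; Model I always stays. The test is two-sided by default —
a distribution shifted in either direction signals a structurally
miscalibrated model — with a one-sided option (`alternative = "less"`)
for users who only want to guard against inflation toward smaller
p-values.

Each TF is then ranked by its minimum p over the acceptable models
(`rankCandidates()`); the model attaining it is the TF's most likely
regulation route, with ties resolved to the lower-numbered (more
parsimonious) model. Ranking ties break by larger overlap count, then by
identifier — an invented but deterministic order. A TF with min p ≤ 0.01
is a valid finding; a perturbed TF is correctly identified when it is
valid and ranks in the top 20 (`correctlyIdentified()`). No
multiple-testing correction is applied anywhere: the thresholds 0.01 and
0.005 are calibrated operating points on raw p-values, and all threshold
comparisons are inclusive.

Parameters that matter, with defaults:

| parameter | default | role |
|---|---|---|
| `scoreThreshold` (LLS) | 4, strict `>` | drop low-confidence TF-DNA edges at load |
| `minSize` | 4 genes | candidate filter: max model-set size must reach it |
| `alpha` | 0.005 | rank-sum acceptability threshold |
| `validP` | 0.01 | valid-finding threshold on min p |
| `topK` | 20 | rank gate for correct identification |
| DEG criteria | p ≤ 0.01, &#124;z&#124; ≥ 2, &#124;fold&#124; ≥ 2 | inclusive, per statistic |

## The synthetic generator

`generateNetwork()` draws a layered network in which TF identifiers double
as their coding genes: each TF receives `1 + Poisson(meanOutDegree − 1)`
transcription targets (so the configured mean is exact and every TF has at
least one target), a `cascadeFraction` share of which are other TFs;
TF → TF kinase edges and modulator → TF edges (modulators drawn from
transcribed background genes, so the X role can actually fire) are then
added at configured counts. `simulatePerturbation()` inverts the inference
task: a true TF and true model are fixed, every gene of that model's set
enters the DEG list with probability `tpr`, every other universe gene with
probability `fpr`. Network generation and DEG sampling use separate,
restored RNG streams, so all outputs are pure functions of (parameters,
seed) and changing the noise rates never changes the network.

Default scenario: 140 TFs over 6000 background genes — the scale band of
the yeast candidate set the method was designed around — with mean
out-degree 20 (large enough that every model layer has mass while the
size-4 candidate filter still bites), cascade fraction 0.15, 60 kinase
edges, 30 modulators, tpr 0.8, fpr 0.02. One full
`recoveryExperiment()` replicate at this scale scores 140 TFs × 6 models
and runs in milliseconds once the sets are built; the test suite uses 100
replicates at full scale and smaller networks (8–40 TFs) for the
structural property checks.

What the generator emulates: layered topology, PTM shortcuts, noisy DEG
calling with independent per-gene errors. What it does not: correlated
expression noise, signed (activation/repression) regulation, cooperative
or competitive TF complexes, condition-dependent edge activity, and any
expression *magnitudes* (only DEG membership is modeled). Passing
recovery tests therefore demonstrate the machinery's correctness and its
behaviour under membership noise — not performance on real microarray
data, where edge-map incompleteness and correlated biology dominate.

## Numerical and degenerate-input choices

* Hypergeometric tails come from `stats::phyper(k − 1, K, N − K, n,
  lower.tail = FALSE)`, stable to N ~ 10^5; the tests verify it against
  exhaustive enumeration of binomial-coefficient ratios for N ≤ 25 at
  1e-12.
* An empty DEG set scores p = 1 everywhere, with a warning; an empty
  universe is an error.
* An empty true downstream set in the simulator warns and draws DEGs from
  the background alone.
* Acceptability with fewer than two candidate TFs is an error (a rank-sum
  test over one point is meaningless); a rank-sum p of exactly α is
  rejection (inclusive thresholds throughout).
* p-values are carried and written at full double precision; rounding
  (3 d.p. for Jaccard, half-up integer percentages for prediction rates)
  happens only at presentation.
* Identifier handling is case-preserving exact match; any ORF/gene-name
  aliasing must happen upstream.

## Evaluation conventions

`confusionVsGold()` counts TP/FP/FN after removing predictions the
experiment never profiled — an unprofiled prediction is neither confirmed
nor refuted, so it is excluded rather than charged as a false positive.
Gold sets built by `goldFromFoldChange()` use signed fold-change ratios
(−3.3 means 3.3-fold down) with an explicit `log2Input` flag for log-scale
inputs. `jaccardScore()` is TP/(TP+FP+FN).

## Known limitations

* The six fixed topologies are a deliberate truncation of model space;
  regulation routes outside them (longer cascades, TF combinations) are
  invisible by design.
* Performance on real data is bounded by the completeness of the TF-DNA
  and PTM edge maps; absent edges silently shrink downstream sets.
* The acceptability filter is a population-level gate: it can discard a
  model that is genuinely right for one TF when that model misbehaves
  across the candidate population (the HSF1-style near-threshold rank drop
  is the expected cost), and it needs a reasonably sized candidate pool to
  be meaningful.
* Unsigned edges mean activation and repression are indistinguishable;
  a repressed and an induced target count the same.
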