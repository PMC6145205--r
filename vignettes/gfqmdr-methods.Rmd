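---
title: "Generalized fuzzy MDR for quantitative traits: model and design notes"
author: "gfqmdr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized fuzzy MDR for quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfqmdr)
```

## The problem

Multifactor dimensionality reduction (MDR) detects gene-gene interactions
(epistasis) by collapsing the $3^m$ joint genotypes of an $m$-marker set into
a single class variable: each multi-locus genotype "cell" is labeled with the
trait category it over-represents, and the labeling is scored as a
classifier.  Classic MDR targets binary case/control status.  Many traits of
interest, however, are quantitative (HDL concentration, lesion size, percent
immunosuppression), and dichotomizing them discards most of their
information.

`gfqmdr` implements a quantitative-trait MDR in which the trait is first
discretized into $J$ ordinal levels (default $J = 3$: low, average, high) and
each cell labeling is scored with a *generalized fuzzy balanced accuracy*.
The key idea is that membership of a trait value in a level is graded, and
the grading is allowed to go negative: a sample whose trait sits far from a
level counts *against* assigning that level.

## Interval schemes and membership functions

An `IntervalScheme` partitions the observed trait range
$[Q_{\min}, Q_{\max}]$ into $J$ intervals with borders
$b_0 < b_1 < \dots < b_J$ and midpoints $P_j = (b_{j-1} + b_j)/2$.  Two
fitting rules are provided:

* `equalLengthScheme(trait, J)` — equal-width intervals; the robust choice
  for traits with unknown shape (used for the real-data style analyses).
* `deviationScheme(trait)` — interior borders at $\mu \pm \sigma/2$; for an
  approximately normal trait this yields level proportions of about
  31/38/31%.  It errors when a border falls outside the observed range
  (an empty level); callers can fall back to equal-length intervals.

The scheme is fitted once on the full trait, before cross-validation: the
discretization is part of the problem statement, not of the per-fold model
fit.

The **traditional family** `muTraditional()` is piecewise linear with range
$[0, 1]$: boundary levels saturate at 1 beyond their own midpoint and ramp to
0 at the adjacent midpoint; interior levels are triangular.  The $J$ levels
form a partition of unity on the observed range.

The **extended family** `muExtended()` has range $[-1, 1]$.  The low level
equals 1 up to $P_1$, descends linearly through 0 at $P_2$ to $-1$ at $P_3$,
and is $-1$ beyond; the high level mirrors it.  Two numerical choices are
deliberate:

* With *unequal* interval widths the descending branch, continued at the
  slope defined between the first two midpoints, can pass $-1$ before
  reaching the far midpoint; we clip it at $-1$ so the documented range
  bound holds for every scheme.  With equal widths the clip never binds and
  the piecewise forms are exact.
* The *middle* level keeps its two linear slopes without clamping; its
  infimum on the observed range is $-0.5$ under equal widths.  Clamping it
  would break the simple transformation identities that relate the two
  families, and no trait value inside the observed range can drive it
  anywhere near $-1$.

For $J > 3$ (not used by default) interior levels continue their triangular
slopes past the adjacent midpoints and clamp at $-1$ one further midpoint
away, preserving the $J = 3$ geometry.

## The classifier and its score

For a marker set $S$ with cells indexed by $i$ and levels by $j$:

* per-cell counts $n_{ij}$ accumulate the **extended** membership of each
  training sample in cell $i$ for level $j$;
* class sizes $n_{+j}$ accumulate the **traditional** membership of all
  training samples (so they stay non-negative).

Each non-empty cell gets the label
$c(i) = \arg\max_j \; n_{ij} / n_{+j}$ (ties to the lower level; cells with
no training samples stay unlabeled), and the model score is the fuzzy
balanced accuracy

$$\mathrm{score} = \frac{1}{J} \sum_i \frac{n_{i,c(i)}}{n_{+c(i)}},$$

with unlabeled cells and zero-size classes contributing 0.  Using the
extended family in the numerator is what distinguishes the generalized
scorer: two cells with the same traditional-membership mass can differ
because samples far from the assigned level penalize it.

Three baselines share the search machinery and differ only in counting
family and score:

| method  | per-cell counts  | class sizes      | score |
|---------|------------------|------------------|-------|
| gfqmdr  | extended         | traditional      | fuzzy balanced accuracy |
| fqmdr   | traditional      | traditional      | fuzzy balanced accuracy |
| mdr     | crisp indicator  | crisp indicator  | mean per-class recall |
| omdr    | crisp indicator  | crisp indicator  | Kendall tau-b (true vs predicted level) |

When every trait value sits exactly on an interval midpoint, the traditional
counts reduce to integer counts and all scorers coincide — *provided* each
cell mixes at most adjacent categories.  (A sample at $P_1$ contributes $-1$
to the high level's extended count, so a cell mixing the extreme categories
can be labeled differently by the crisp and extended rules; the equivalence
tests construct their fixtures in the adjacent-mix regime where the
reduction is exact.)

## Search, cross-validation consistency, and p-values

`crossValidatedSearch()` enumerates all $\binom{m}{\text{order}}$ marker
sets under $L$-fold cross-validation (default $L = 10$, stratified by crisp
level so no fold loses a category).  Per fold the top-$K$ sets by training
score (default $K = 3$) are retained and scored on the held-out fold, where
the fuzzy counts are recomputed on the held-out samples using the training
labels and the full-data scheme.  Each retained set reports

* **MTSBCA** — its maximum testing balanced classification accuracy across
  the folds that retained it, the primary ranking key;
* **GCVC** — the number of folds in which it was top-$K$, the tie-break;
* marker indices as the final deterministic tie-break.

Held-out samples falling into unlabeled cells contribute 0 to the fuzzy and
recall scores and are excluded from the tau-b table (no prediction exists).

`permutationPValue()` tests a candidate by permuting the trait against the
genotype rows.  The observed statistic is the candidate's full-data training
score.  Two nulls are available:

* `max_over_all` — per permutation, the maximum score over *every*
  same-order marker set.  Because the identified candidate is itself a
  maximum, this selection-aware null is the calibrated choice and is what
  the type-I-error machinery uses.
* `candidate` — recompute only the candidate's own score; much cheaper and
  anti-conservative in general.  The hit-ratio experiments use it because
  an exhaustive null over $\binom{100}{2}$ pairs times 1000 permutations
  per replicate is computationally out of reach on any hardware, and at the
  settings where hit ratios are interpreted the significance gate is
  saturated (true-signal p-values are 0 to permutation resolution), so the
  choice does not move the ratio.

Empirical p-values are reported without the $+1$ correction (`plusOne`
flag available): an observed score exceeding every permuted value yields
exactly 0, matching how strong interactions are conventionally reported.

## The synthetic-data generator

`simulateDataset()` emulates a two-locus quantitative-trait epistasis study:

* **Genotypes** — independent biallelic markers in Hardy-Weinberg
  equilibrium at a common minor allele frequency (0.2 or 0.4 in the study
  designs).  This replaces LD-preserving resampling from reference panels:
  for detection experiments the non-causal markers only need to be
  exchangeable null background, so independent HWE sampling preserves the
  experimental logic while keeping the generator self-contained.  Real LD
  structure, population stratification and genotyping error are *not*
  emulated, so passing tests speak to the method's behavior under clean
  nulls and clean signals, not to robustness on real cohorts.
* **Trait** — for causal pair(s) with penetrance grid(s) $f$, each sample
  draws from $\mathcal{N}(\sum_t w_t f_t[g_1, g_2],\; \sigma^{*})$.
  $\sigma^{*}$ is interpreted as the *standard deviation* (a
  `sigmaAsVariance` flag flips this): the study's difficulty gradient
  (near-perfect detection at $\sigma^{*} = 0.1$, severe degradation by
  $0.5$) only makes sense on the sd scale, where $\sigma^{*} = 0.1$
  separates the canonical cell means 0.01/0.25/0.5 by at least 2.4 sd.
* **Grids** — `defaultModelGrids()` ships five distinct 3x3 layouts over
  the canonical mean levels $\{0.01, 0.25, 0.5\}$ (checkerboard, gradient,
  diagonal, corner, center).  The original five figure layouts are not
  recoverable from text, so these are editable synthetic stand-ins; at
  $\sigma^{*} = 0.1$ detection is insensitive to the layout, and any grid
  can be overridden from a YAML/JSON file.
* **Null designs** — genotypes as above, trait standard normal and
  independent; MAF fixed at 0.2 (the generator does not state a null MAF
  and the null is exchangeable in it).
* Causal pairs sit at markers (1,2) (and (3,4) for a second model) —
  irrelevant under exchangeable markers, recorded in metadata for scoring.

Replicate $r$ of an experiment reseeds everything from
$\text{seed} + r$, so any single replicate can be rerun in isolation and
parallel execution cannot change results.

## Experiment runners and validation problem sizes

* `hitRatio()` — fraction of replicates in which the causal pair is the
  top-ranked candidate passing the permutation gate at $\alpha = 0.01$
  (per-model tallies for mixtures).  Validated at the study's full scale:
  100 markers, 100 replicates, $n = 800$, $\sigma^{*} = 0.1$ for the easy
  settings (printed hit ratios of 100%, checked within 10 points), and 50
  replicates for the easy-vs-hard gradient check
  ($n = 800, \sigma^{*} = 0.1$ versus $n = 200, \sigma^{*} = 0.5$, at
  least a 20-point drop).
* `typeIError()` — on null designs ($m \in \{10, 15, 20\}$,
  $n \in \{200, 400, 600\}$), the fraction of replicates whose strongest
  pair has permutation $p < 0.01$ under the max-over-all null.  The
  published procedure uses 1000 replicates and 1000 permutations; the
  package's validation and the acceptance script run 200 x 200 and compare
  through binomial confidence intervals.  At 200 permutations the
  achievable p-values below 0.01 are $\{0, 0.005\}$, so exact discrete
  calibration puts the rejection rate at $2/201 \approx 0.995\%$.
* `realdataTable()` — the per-method, per-order top-$k$ MTSBCA/GCVC layout
  used to compare scorers on a single dataset.

## Known limitations

* The exhaustive search is $O(\binom{m}{\text{order}} \cdot n \cdot L)$;
  orders above 4 or marker counts in the thousands need pre-filtering,
  which is out of scope here.
* The fuzzy balanced accuracy is not bounded by 1 in pathological labelings
  (negative counts can inflate a ratio); only the perfect midpoint-aligned
  classifier is guaranteed score 1.
* Covariate adjustment, parametric trait models, and entropy-based
  interaction statistics are intentionally not implemented.

## A worked call

```{r example, eval = FALSE}
cfg <- simulationConfig(n = 400, m = 20, maf = 0.4, sigma = 0.2, seed = 11)
x <- simulateDataset(cfg)
res <- crossValidatedSearch(x, order = 2, folds = 10, seed = 1)
res <- computePValues(res, x, nPerm = 1000, seed = 2)
finalSelection(res, alpha = 0.01)
```
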