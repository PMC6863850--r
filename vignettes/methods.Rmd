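---
title: "Evidence integration for drug-target identification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence integration for drug-target identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistical model

DrugBayes treats "do these two drugs share a binding target?" as a
two-class problem scored by a product of per-channel likelihood ratios.
For each data type the similarity of a drug pair is a scalar score:

* **gi50**, **cmap** — Pearson correlation of numeric profiles over the
  jointly observed conditions (range $[-1,1]$). A pair is scorable only
  with at least three shared observations and non-constant restricted
  profiles; anything else is *masked*, never coerced to 0, because 0 is a
  meaningful correlation.
* **bioassay**, **sideeffect** — Jaccard index of positive features
  (range $[0,1]$). Bioassays additionally require at least one co-tested
  assay; side-effect terms are presence/absence over the full vocabulary.
* **structure** — DICE coefficient
  $2\sum_k \min(c_a,c_b) / (\sum_k c_a + \sum_k c_b)$ on atom-pair count
  fingerprints. The atom descriptor is (element, heavy-neighbor count,
  aromatic flag) and the pair key adds the uncapped shortest bond-path
  length; this deliberately simple descriptor keeps every fingerprint
  hand-checkable (ethane has exactly one feature; propane vs butane has
  DICE $4/9$). SMILES parsing and aromaticity perception are delegated to
  OpenBabel via ChemmineR/ChemmineOB; the fingerprint itself is computed
  here.

Pairs of annotated drugs are labeled ST (target sets intersect) or
non-ST. Per channel, scores are binned into $B = 20$ evenly spaced
intervals over the channel's *natural* range (not the observed min/max,
so bins mean the same thing across datasets), and each bin gets

$$\hat L_b = \frac{(ST_b + \alpha)/(N_{ST} + \alpha B)}
                  {(nonST_b + \alpha)/(N_{nonST} + \alpha B)}$$

with a Laplace pseudocount $\alpha = 1$ by default — the raw ratio
divides by zero in empty bins, and sparse extreme bins are exactly where
queries land. An exponential curve $L(s) = a\,e^{bs}$ is then fit by
least squares on $\log \hat L_b$ at the bin centers, weighted by bin
occupancy so that well-populated bins dominate; the fitted curve, not the
raw ratios, scores new pairs. If all scores fall in one bin the model
degenerates cleanly to a constant.

The total likelihood ratio of a pair is the product over channels,
justified by the empirical near-independence of the similarity types
(see the generator section). A channel missing for a pair contributes
$L(m)$ where $m$ is the median of all observed scores of that channel —
imputation happens after the similarity-to-likelihood conversion, so a
missing channel is neutral-ish evidence rather than a fabricated score.
The TLR is reported as the raw product; all cutoffs (100, 500, the
operating cutoffs below) live on this raw scale.

Numerical guards: query scores marginally outside the range (floating
point noise) are clamped to the boundary; scores beyond 5% of the span
are a hard error. $\log$-TLR equals the sum of per-channel
log-likelihoods to $10^{-12}$ relative, which the tests assert.

## Voting, the high-confidence filter, clustering

A query's *shared-target predictions* are its annotated partners with
TLR at or above a cutoff. Each prediction votes for every known target
of its partner, weighted by the raw TLR (a log-TLR option exists; raw is
the default because the evidence scale is the odds scale). Ties in vote
mass break by supporting-prediction count, then maximum supporting TLR,
then lexical target ID — deterministic and documented. The
high-confidence filter confirms the top-voted target only if (i) it
occurs in the known targets of a *strict majority* of predictions and
(ii) it occurs in the single highest-TLR prediction; otherwise it
abstains. It never substitutes a lower-ranked target.

For mechanism-of-action analysis the distance between drugs is exactly
$1/\mathrm{TLR}$. Average-linkage (UPGMA) clustering runs on the complete
distance matrix; a missing TLR inside a clustering set is a hard error
naming the pair, because silently imputing distances would fabricate
mechanism structure. Drugs are sorted lexically before `hclust` so equal
merge heights resolve deterministically. Shared-target networks keep
edges with TLR ≥ cutoff (default 500) and retain an orphan node only
with at least two qualifying edges to annotated drugs. Classical
(Torgerson) MDS embeds the same distances for overview plots.

## Evaluation machinery

Cross-validation is at the *pair* level, stratified so each fold keeps
the global ST:non-ST ratio to within one pair per class; models are
refit per training fold (bins, curve, medians) and held-out TLRs are
pooled. Pair-level CV lets one drug appear on both sides of the split;
this leakage is inherent to the design being emulated and is documented
rather than hidden — the fold assignment is seeded and reproducible.
AUROC uses the Mann-Whitney half-credit-for-ties formulation (tested
against a brute-force concordance count), KS separation the maximum ECDF
difference with the asymptotic two-sample p-value, and the channel-subset
analysis computes one pooled-fold AUROC per nonempty channel subset under
two availability policies (require all channels present, or impute
medians). Leave-one-out voting accuracy refits the model with every pair
involving the held-out drug removed.

The *operating cutoff* for orphan screening is read off the
true/false-positive ratio curve as the smallest grid cutoff at which
predicted shared-target pairs are majority-true (TP/FP ≥ 1). With a
~4.5% ST base rate that is a ~22-fold enrichment — the natural elbow at
which predictions switch from mostly-wrong to mostly-right; deeper
cutoffs trade coverage for precision and are exposed to the user.

## The synthetic universe: what it emulates and what it does not

The generator plants the truth the rest of the package is scored
against. Each drug receives one guaranteed target plus a
Poisson(0.15)-distributed number of extras, drawn from a Zipf-skewed
popularity distribution (exponent 0.5 over 50 targets by default) —
real annotation corpora are heavily imbalanced, and that imbalance is
what makes low voting cutoffs genuinely error-prone (popular targets
steal votes), reproducing the rising accuracy-vs-cutoff curve. A
configurable fraction (10%) of drugs are emitted as orphans: features
present, annotation withheld but kept in the truth slot.

Every channel derives from *channel-specific, mutually independent*
latent target signatures: a Gaussian profile per target for gi50/cmap, a
fixed-size latent feature set for bioassay/side effects, a sparse count
template for structure. A drug mixes its targets' signatures and adds
channel noise; the per-channel `signal` parameter (default 0.8) scales
the mixing weight. Three design points matter:

* **Channel gains are asymmetric**, mirroring the strong/weak pattern of
  real heterogeneous drug data: at signal 0.8 the realized KS D between
  ST and non-ST scores is ≈ 0.50 (gi50), 0.13 (cmap), 0.49 (bioassay),
  0.14 (side effects), 0.55 (structure). Two near-uninformative channels
  are kept deliberately: integration must tolerate them.
* **Set sizes carry no target information.** Latent sets have fixed
  size, multi-target drugs subsample their combined repertoire to
  single-target size, and fingerprint templates average over targets.
  Early versions let a drug's positives count grow with its target
  count, which coupled channels through a shared drug attribute and
  inflated cross-channel correlation; with the decoupling, the maximum
  absolute cross-channel Pearson correlation of similarity scores is
  ≈ 0.08 at default size — the regime in which the naive Bayes product
  is defensible.
* **At signal 0 every channel is pure noise by construction** (the
  latent weight is exactly zero), so the held-out AUROC of the fitted
  TLR is 0.5 within sampling error — the null the tests assert.

Missingness removes whole drugs from a channel (rows of `NA`, or absence
from the binary tables) at rate 0.1 per channel. The structure channel
is generated directly as fingerprint count vectors — generating actual
molecules with controlled pairwise DICE is a research problem in its own
right; the SMILES → fingerprint path is covered by real fixture
molecules (methane through toluene) with hand-enumerated fingerprints.

With `moaSplit = TRUE` the first target is planted with two
sub-mechanisms: its drugs split into two groups whose signatures differ
in every channel (offset weight 1.5 for profiles, ~50% template sharing
for sets) while all of them still share the target. Cutting the 1/TLR
average-linkage dendrogram at $k = 2$ recovers the split exactly
(adjusted Rand = 1), with or without the structure channel.

What the generator does **not** emulate: real marginal distributions of
GI50 or expression fold changes, pharmacological co-occurrence structure
of side effects, chemical-series structure in fingerprints, or
inter-channel dependence (the model's known blind spot). Passing tests
therefore demonstrate correctness and calibration of the machinery under
the independence regime the method assumes, not performance on any
particular real corpus.

## Problem sizes and defaults

The default universe has 300 drugs (≈ 36,000 annotated pairs), which
gives each target ≈ 6 carriers — enough for voting to be a fair test
while keeping the full test suite and the acceptance script in the
minutes range on a single core. The channel-integration benchmarks
(subset AUROC, TP/FP curves) use a 200-drug universe (≈ 16,000 labeled
pairs). Orphan recovery is measured over orphans meeting the screening
eligibility rule — data in at least three of the five channels, the same
default `runScreen` applies; orphans whose planted target has no
annotated carrier count as failures (no voting scheme can name a target
absent from the annotation space).

## Known limitations

* The exponential family for $L(s)$ is an assumption; channels whose
  true bin-ratio profile is non-monotone would be poorly served (a
  constant fallback exists only for the degenerate single-bin case).
* Pair-level CV leaks drug identity across folds; a drug-disjoint CV is
  not implemented because the evaluation being reproduced is pair-level.
* The high-confidence filter's strict-majority rule is sensitive to the
  prediction count at the cutoff; with a single prediction it confirms
  iff that prediction carries the top target.
* Vote weighting by raw TLR lets one extreme pair dominate a tally; the
  log-TLR option trades that for popularity bias.
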