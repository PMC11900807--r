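---
title: "Methods: post-docking screening analysis for odorant receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-docking screening analysis for odorant receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscreen)
```

## Scope and assumptions

`orscreen` begins where docking ends. It assumes (a) a molecule library
with valid SMILES; (b) per-receptor docking scores in kcal/mol-like
units where more negative means stronger predicted binding; (c) an
experimental activity panel (binary labels, or p-values dichotomized at
a strict threshold, 0.001 by default) for calibration; and (d) a
per-receptor binding-pocket descriptor table produced by an external
cavity-analysis tool. Docking itself, receptor structure modeling,
cavity detection and 3-D ligand preparation are out of scope; their
outputs are consumed as data.

Score orientation is fixed throughout: ranking, top-fraction cuts, ROC
and enrichment statistics always consume ranks derived from ascending
score order (most negative first), never sign-flipped scores, which
removes a whole class of orientation bugs.

## The odorant-likeness filter

Volatile, odorant-like molecules occupy a narrow physicochemical
window. The filter retains molecules with molecular weight at most
400 g/mol, at most 25 heavy atoms, at most 10 heteroatoms, and
calculated logP between -1 and 7; all bounds are inclusive ("not
exceeding", "no more than" and "ranging between" are read as closed
intervals). Molecular weight and the Crippen-type atomic-contribution
logP come from Open Babel (via ChemmineOB) on the canonical SMILES; the
logP method is pinned so that filter outcomes are reproducible. Atom
counts are exact counts over the parsed structure; a heteroatom is any
atom that is neither carbon nor hydrogen. Multi-fragment (salt/mixture)
SMILES are reduced to their largest fragment before descriptor
computation, with a logged message. Unparseable SMILES are skipped with
a warning at library load but are hard errors in per-molecule
operations, so silent data loss can only happen where it is visible and
counted.

## Ligand-efficiency rescoring

Empirical scoring functions sum per-atom interaction terms, so large
molecules accumulate both more favorable terms and more error; raw
scores therefore rank by size before they rank by fit. The three
weightings divide the raw score $s$ by an increasing function of the
heavy-atom count:

$$\mathrm{LE} = s/\mathit{HA}, \qquad
  \mathrm{LEln} = s/(1 + \ln \mathit{HA}), \qquad
  \mathrm{LESA} = s/\mathit{HA}^{2/3}.$$

LE removes a strictly proportional size effect; LESA corresponds to a
surface-area-like (two-thirds power) growth law; LEln is the mildest
correction. All three are strictly increasing in $\mathit{HA}$ for
fixed $s < 0$ (size is penalized) and rank-preserving within any set of
molecules sharing one heavy-atom count. Heavy atoms are counted on the
2-D structure, not on docked poses.

## Calibration

For each receptor and scoring method the package computes:

* **ROC AUC** as the Mann–Whitney statistic: the fraction of
  (active, inactive) pairs in which the active molecule scores better,
  ties counted 0.5. This is exactly the area under the empirical ROC
  curve and requires no interpolation choices.
* **Enrichment factors** over a fraction grid (default 1%–100% in 1%
  steps): $EF(f) = \frac{\text{actives in top } k}{k} \big/
  \frac{\text{actives}}{N}$ with $k = \max(1, \mathrm{round}(fN))$,
  rounding half up. The reported maximum EF is the maximum over the
  grid, since an optimal reporting fraction is not otherwise defined.
* **The optimal top fraction** maximizing TPR/FPR over the same grid.
  When FPR is zero the continuity correction $0.5/\#\text{inactives}$
  is substituted, which keeps the ratio finite without reordering
  non-degenerate comparisons. Ties resolve to the smallest fraction.

Workflow thresholds are medians across receptors (midpoint convention
for even counts): the chosen top fraction is the median per-receptor
optimum for the best-performing method, computed over non-pheromonal
receptors only — pheromone receptors behave differently enough under
raw scoring that they would distort the threshold — and the non-binder
fraction is the median of (first rank at which TPR reaches 1)/N. Both
conventions are configurable.

## Triage

Triage is a four-step partition. Per receptor, the top
$k = \max(1, \mathrm{round}(0.06\,N))$ molecules are candidate binders.
A molecule's promiscuity frequency is the share of receptors whose top
set contains it; at or above 0.7 (the threshold is inclusive, and
configurable) the molecule becomes a suspected decoy — an artifact of
the scoring function rather than plausible polypharmacology — and is
removed from every binder set. Decoy status is global; binder and
non-binder status are per-receptor. The worst
$\lfloor 0.45\,N \rfloor$ ranks are potential non-binders. With a
single receptor the frequency is degenerate (0 or 1), so at any
threshold at most the top set itself is flagged; this is intended
behavior, not an error. The receptor subset over which frequencies are
computed is an explicit argument, because a screening campaign may wish
to exclude receptor classes from the decoy definition.

Prediction quality against experimental outcomes is summarized by the
binder-versus-active contingency: precision (a percentage), accuracy,
TPR and FPR. Undefined ratios (empty denominators) are reported as
`NA`, never coerced to zero.

## Chemical space

Fingerprints are circular (Morgan-type) radius-2, 2048-bit vectors
computed by iterative neighborhood hashing on the molecular graph.
The initial atom invariant is (element, heavy degree, total bond
order); each round hashes an atom's invariant with the sorted
(bond order, neighbor invariant) list, so the result is independent of
atom input order, and SMILES are canonicalised first so equivalent
writings of one molecule yield identical bits. The implementation is
native to the package; its contract is determinism and discrimination,
not bit-level equality with any other toolkit.

The 2-D embedding is classical (Torgerson) multidimensional scaling of
fingerprint distances (Euclidean on raw bits by default; Jaccard is
available because the metric choice is scientifically material).
Clustering on the embedded plane is a density method in the HDBSCAN
family implemented here: single linkage on mutual-reachability
distances (core distance = distance to the `n_neighbors`-th nearest
neighbor), a cut at the largest gap between consecutive merge heights,
and dissolution of groups smaller than `min_cluster_size` (default 30)
into an explicit noise label (`0`). Unlike stochastic
neighbor-embedding pipelines this procedure is fully deterministic:
identical inputs give identical labels for any seed, and input order
cannot matter because molecules are processed in sorted-id order and
clusters are renumbered canonically (densest first, ties by smallest
member id). The `min_dist` parameter of the configuration is recorded
in the result for provenance but is not consumed by the deterministic
embedding. Fewer points than `min_cluster_size` are all noise by
construction.

Cluster consistency compares each cluster's mean intra-cluster
Tanimoto similarity with the similarities between cluster *medoids*
(the member maximizing mean similarity to its own cluster). A centroid
in bit-vector space is not itself a fingerprint, so the medoid is the
faithful realization of "cluster center"; the check passes when every
cluster is internally more similar than it is to any other center.
Two all-zero fingerprints have Tanimoto similarity 1 by documented
convention (identical, featureless).

Candidate selection takes one best-scoring available molecule per
cluster, five for clusters containing a known ligand (those clusters
are where cheap confirmations live, and the published protocol checked
the availability of the top five there). Unavailable molecules fall
back to the next best in the same cluster; noise molecules are never
selected; clusters are reported densest first.

## Pocket-descriptor tuning model

Receptor tuning breadth — the number of panel molecules a receptor
responds to — is regressed by ordinary least squares on named pocket
descriptors (volume in cubic angstroms, SASA in square angstroms,
hydrophobicity and polarity scores as produced by the cavity tool and
treated as opaque columns). Counts are modeled as an unbounded
continuous response; no count GLM is attempted because at panel scale
(n = 17 receptors) the linear fit is the transparent choice and
matches how such analyses are reported. Metrics are in-sample — the
Pearson correlation between fitted and observed counts, and RMSE with
denominator n — with an optional leave-one-out variant for honesty
about overfitting. Rank-deficient designs (duplicated, collinear or
constant columns) and constant responses are hard errors naming the
offending columns, not silent coefficient drops. Adding a variable can
never lower the in-sample correlation; the package exposes
`compare_tuning_models()` to make such nested comparisons explicit
rather than implied.

## The synthetic-data generators

`simulate_screen()` generates the statistical structure the workflow
assumes, not docking physics. Its score model is

$$s(r, m) = \beta_0 - \mathit{HA}_m\,
  (b + e\,\mathbb{1}[\text{binder}] + d\,\mathbb{1}[\text{decoy}]
   - \eta_{rm}), \qquad \eta_{rm} \sim N(0, \sigma),$$

i.e. every contribution — the size bias $b$, the binder signal $e$,
the decoy artifact $d$, and the noise — scales with the heavy-atom
count, reflecting the per-atom accumulation of terms in additive
empirical scoring functions. This is precisely the regime in which
dividing by $\mathit{HA}$ restores a homoscedastic, size-neutral
ranking, which is the scientific premise of ligand-efficiency
rescoring. With constant-variance noise instead, the extreme top of
the LE ranking is dominated by small-molecule noise and no parameter
choice lets a size-corrected method win on early enrichment; the
multiplicative form is therefore a modeling decision, not a tuning
knob.

Planted decoys are drawn from the largest third of the library and
receive their own over-scoring term $d$ (default $3e$) on **every**
receptor while being labeled inactive everywhere. Both choices are
constitutive: a "promiscuous top-scorer" that neither ranks near the
top nor recurs across receptors would simply be background. Because
the noise re-rolls per receptor, decoys at the default effect size are
strong but imperfect top-rankers; constructions used to test the
frequency filter raise $d$ until the decoys genuinely occupy every top
set, which is the precondition under which near-complete recovery is a
meaningful claim.

Default conditions (frozen; chosen to emulate a de Fouchier-style
calibration panel): 15 non-pheromonal receptors, 400 molecules,
heavy atoms uniform on 4–25, 10% planted binders per receptor, 2%
decoys, $\beta_0 = -0.5$, $b = 0.6$, $e = 0.15$, $d = 0.45$,
$\sigma = 0.2$ (all in score units per heavy atom where applicable).
Under these conditions raw scoring is weakly discriminative and
heavy-atom weighting recovers most of the planted signal, which is the
qualitative regime the calibration stage exists to detect. Synthetic
SMILES come from a small grammar (alkyl/ether/amine chains, benzene
rings, terminal carbonyls) that hits exact heavy-atom counts and
always parses; it emulates the size and element composition of
volatile panels, **not** their pharmacology, stereochemistry, or
tautomeric richness — so passing tests demonstrate the statistical
machinery, never the docking accuracy obtainable on real receptors.

`simulate_pockets()` draws descriptors uniformly from documented
ranges (volume 200–700 cubic angstroms, SASA 300–900 square angstroms)
and builds counts from a linear predictor plus Gaussian noise,
truncated at zero and rounded — the truncation and rounding slightly
bias coefficient recovery at small n, which the parameter-recovery
tests tolerate explicitly. Default coefficients encode the expected
directions (larger pockets narrow the spectrum; hydrophobicity
broadens it).

All generators are pure functions of (configuration, seed).

## Numerical conventions

* Top-set size: $k = \max(1, \mathrm{round}(fN))$ with round-half-up,
  because R's banker's rounding moves cut boundaries.
* Ranking ties break lexicographically by molecule id, making every
  threshold cut reproducible.
* AUC ties credit 0.5 per tied pair; medians of even counts use the
  midpoint.
* Duplicate score rows keep the most negative value with a warning;
  multi-pose logs keep the first (best) pose.
* Problem sizes in the test and acceptance suites (15 × 400 screens,
  20 seeds, 17-receptor pocket panels) are the package's chosen study
  conditions, matching the scale of the calibration data the workflow
  is designed around.

## Limitations

* The pipeline is only as good as the docking scores it consumes; the
  calibration stage measures, but cannot repair, a scoring function
  with no signal.
* The synthetic generators produce idealized Gaussian structure —
  real screens have heavy-tailed scores, correlated receptors, and
  assay noise on the activity labels.
* The bundled pocket regression runs on a clearly-labelled synthetic
  stand-in panel; reproducing published fit statistics requires the
  original externally-computed descriptor table.
* Agonist/antagonist distinction, 3-D conformer effects and
  interaction fingerprints are out of scope.
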