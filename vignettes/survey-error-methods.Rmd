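---
title: "Methods: quantifying false-positive errors in repeated botanical surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying false-positive errors in repeated botanical surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Repeated presence-only surveys of the same site by independent observers
make two error processes visible at once. A species that is present may be
missed (a false negative), and a species that is absent may be recorded
anyway (a false positive) — through misidentification, a slip of the pen,
or overconfidence. False positives are the more corrosive of the two:
they cannot be repaired by extra effort, they inflate apparent ranges of
rare species, and they persist in datasets indefinitely. `surveyerr`
implements an analysis pipeline for such data: classification of records
against a trusted site reference, detection-probability and error-rate
estimation, combination of surveys under raised acceptance thresholds,
a phylogenetic-signal test of where errors fall on the tree of the
regional flora, and a rarity model for which species attract errors.
A synthetic observer world with complete ground truth closes the loop:
every estimator can be checked against known generative parameters.

## Record classification

Each record carries a raw name as written in the field. Normalisation
squashes whitespace, drops hybrid signs, strips authorship strings
heuristically (the specific epithet is the first purely lower-case
alphabetic token after the genus; abbreviated authors contain periods or
capitals), and collapses infraspecific records to the parent binomial.
There is deliberately **no fuzzy matching**: a name that fails exact match
against the regional checklist is, by definition, a record of something
that does not exist — the *mythical* category. A user-supplied synonym
table is the only sanctioned escape hatch.

Classification is a total function with four mutually exclusive outcomes:

| category | condition |
|---|---|
| `true_positive` | valid species, on the site's accepted list |
| `false_positive` | valid regional species, not accepted at the site |
| `cautious` | genus-rank record of a valid genus |
| `mythical` | name matching no valid taxon (`matched_name` is `NA`) |

"Unreasonable" records (never found at the site) and outright
misidentifications are not distinguishable without the observer's intent,
and all downstream statistics treat them identically, so they are one
`false_positive` class. Survey scoring follows the field-test convention:
correct species count 1, each distinct cautiously recorded genus counts
½ (once per genus, however often it is recorded), expressed as a fraction
of the gold-standard observer's total. The penalty weight for false
positives in an official grade is not standardised, so `score_survey`
reports the false-positive count separately and applies a configurable
penalty defaulting to zero.

## Detection statistics

Detection probability is the raw ratio detections/surveys — deliberately
so; no latent-state occupancy model is fitted, because the site reference
already supplies truth. Per-observer false-positive rates use only
species-rank records: FP/(TP+FP). Cautious and mythical records are
summarised separately and never enter these ratios.

Because sites differ in flora, habitat and survey count, correlations
(false positives vs correct count per observer; genus false-positive
totals vs regional genus size; cautious counts vs genus size; cautious vs
false-positive counts per observer) are computed **per site** and
summarised as the mean of per-site Pearson r with a t-distribution
interval, mean ± t(0.975, n−1)·sd/√n over n sites. Pearson is the
default with a `method` switch; a site where either variable is constant
has an undefined r and is excluded with a warning rather than silently.

## Combining surveys under an acceptance threshold

Raising the evidence threshold for "present" is implemented by combining
k surveys under one of three rules: present in **all** k, in **at least
m** of k, or in **any** (union). Because survey lists differ, the
combination is evaluated by resampling: each resample draws k *distinct*
surveys uniformly without replacement from the site's pool (combining a
survey with itself is meaningless for an agreement rule), scores the
accepted set against the reference (TP/FP/FN), and means are taken over
`n_boot` resamples (10,000 by convention; unit tests use less). For any
site with few surveys the bootstrap means are verified in the test suite
against exhaustive enumeration over all C(n, k) combinations.

Seeding is designed for paired comparisons: each (site, k) cell derives
its own seed from the root seed, and **all rules share that cell's
resample stream**. Rules are therefore compared on exactly the same
survey selections, which makes the monotonicity chain

mean_fp(all of k) ≤ mean_fp(at least m) ≤ mean_fp(union)

hold exactly in every sweep table rather than only in expectation, and
keeps every cell independently reproducible.

Sensitivity is TP/(TP+FN). Specificity needs a true-negative count, which
is ill-defined for an open species pool; the convention used here is the
site's cumulative false-positive pool — every species ever falsely
recorded there — minus the combination's mean false positives. That pool
is the set of absent species observers demonstrably considered plausible.
The absolute size of this pool is arbitrary and shifts only the level of
specificity, never the comparison between thresholds; conclusions should
rest on relative specificity.

## The D statistic

Whether false positives cluster on the phylogeny is tested with the D
statistic for binary traits. The observed quantity is the sum of
sister-clade differences: ancestral nodal values are estimated by
contrast-style weighted averaging (each daughter weighted by the inverse
of its branch length, with the node's own branch extended by the harmonic
term b·c/(b+c) as it is absorbed), and

d_obs = Σ over internal nodes |value(left daughter) − value(right daughter)|.

At a polytomy the node contributes the mean absolute pairwise daughter
difference, which reduces to the binary case at bifurcations. Zero-length
branches are floored at 10⁻⁸ of tree height so inverse-length weights
stay finite. Because the nodal averaging is linear in tip states, the
whole computation is expressed once per tree as a linear operator (a
matrix of signed coefficient differences); evaluating thousands of
permuted or simulated traits is then a single matrix product, which is
what makes the calibration affordable.

d_obs is scaled between two simulated calibrations, each preserving the
observed number of 1-state tips:

- **random**: tip states permuted uniformly; and
- **Brownian threshold**: a continuous trait evolved along branches with
  variance proportional to branch length from root state 0, dichotomised
  at the order statistic matching the observed prevalence (ties broken by
  draw order).

D = (d_obs − mean d_B) / (mean d_R − mean d_B), so D = 1 when the trait
looks permutation-random and D = 0 when it is as clumped as Brownian
evolution; D < 0 (extreme clumping) and D > 1 (overdispersion) are legal
and never clamped. Two p-values are reported with directions chosen so a
clumped trait gives small `p_random` (fraction of permutation d ≤ d_obs)
and an overdispersed trait small `p_brownian` (fraction of Brownian
d ≥ d_obs). The implementation is validated three ways: a four-tip tree
whose d was worked out by hand before any code existed; exact agreement
between the matrix operator and a direct recursive implementation; and
the self-calibration identities — over 200 replicate 200-tip pure-birth
trees the mean D of random traits must sit within 1 ± 0.1 and of
Brownian-threshold traits within 0 ± 0.1, which the acceptance checks
compute in full.

Tree handling (Newick parsing, pruning to the recorded species) is
delegated to `ape`; pruning reports unmatched names explicitly instead of
dropping them, because reconciling survey taxonomy with a reference
phylogeny is a caller-level decision. For genus-level (cautious)
records, `genus_trait_on_tree` marks every tip of a cautiously recorded
genus — one concrete choice among several defensible ones, and
configurable by supplying any 0/1 trait directly.

## The rarity model

Are regionally rare species more likely to be falsely recorded? Counting
false positives per species gives overdispersed counts (most species have
0 or 1), so the response is reduced to binary — was the species ever a
false positive at this site — and modelled per site as a Bernoulli GLM
with logit link against the regional 4 km² occupancy probability, fitted
by IRLS through `stats::glm` and cross-checked in the tests against a
direct likelihood optimisation to 10⁻⁶. The intercept back-transforms
through the inverse logit to the probability that a species with zero
regional occupancy is reported; the slope through the exponential to an
odds factor per unit occupancy. Occupancy is treated as a proportion in
[0, 1] and the scale is recorded in the fit object, since published
coefficient magnitudes depend on that convention. Complete separation is
detected and flagged rather than hidden. Goodness of fit uses the
central third of species by occupancy rank: observed false-positive
proportion ± binomial SE against the model's prediction at the
subgroup's mean occupancy. Sites are never pooled — flora and habitat
differences make each site its own replicate.

## The synthetic world

The generator encodes, as a null model with dials, the structure the
analysis assumes:

| parameter | default | what it emulates |
|---|---|---|
| regional pool | 1000 species, 250 genera | a regional flora with genus structure (genus sizes 1 + negative binomial, adjusted to conserve the pool) |
| occupancy | Beta(0.8, 2.5) | right-skewed regional frequency: most species scarce |
| detectability | Beta(1, 2) | wide 0–1 spread with exactly 75% of species below 0.5 |
| site | 100 species, occupancy-weighted draw | a botanically rich 2–3 ha survey site |
| observer skill | Beta(8, 2) | the fraction of detected species an observer can name, varying widely |
| FP intensity λ | Gamma(shape 2, mean 0.9)/survey | false positives a few percent (≈3–4%) of a survey's records; set analytically from 100 · E[detectability] · E[skill] · (1 − cautious rate) ≈ 25 named true records per survey |
| rarity bias γ | 1 | FP species drawn ∝ (1 − occupancy)^γ |
| genus bias δ | 1 | … · genus_size^δ: errors from species-rich genera |
| cautious rate | 0.05 | genus-only records |
| mythical rate | 0.05 | corrupted, non-existent combinations |

False-positive species are drawn from outside the site **without
phylogenetic structure** — the null under which D should be 1 — while
rarity and genus biases are on by default, so the pipeline should recover
a negative occupancy slope and a positive genus-size correlation; the
end-to-end test asserts exactly these three recoveries. Fake binomials
use globally unique alphabetic epithets, so a cross-genus recombination
is guaranteed invalid, giving mythical records their defining property by
construction.

What the generator does **not** emulate — and what green tests therefore
do not demonstrate about field data: seasonal and habitat-dependent
detectability, within-site spatial structure, observer-specific taxonomic
blind spots, errors in the reference list itself, and name-matching
friction between survey taxonomy and a real phylogeny (synthetic names
match their tree tips exactly). Real reference lists also contain false
negatives that masquerade as observer false positives; the generator's
reference is perfect by construction.

## Numerical choices and reproducibility

Every stochastic stage takes an explicit integer seed; `run_all` derives
per-stage, per-site seeds from one root seed via a deterministic hash
kept below 2³¹, and the run manifest records them together with input
digests, so any stage can be rerun bit-identically. RNG state is always
restored after seeded code, so library calls do not perturb a caller's
stream. Degenerate inputs fail loudly: constant traits, single-class
outcomes, empty names, k larger than the survey pool, agreement
thresholds above k, and mean false positives exceeding the cumulative
pool (an impossibility by construction) are all distinct errors.

Validation problem sizes were chosen as the smallest at which the checked
quantities stabilise: exhaustive-enumeration comparisons use sites of ≤ 6
surveys at 10,000 resamples (3 Monte-Carlo standard errors); D
calibration uses 200 replicates on a 200-tip tree with 1000 permutations
and 1000 Brownian simulations each; GLM recovery uses 200 replicates of
250 species; the end-to-end world uses 4 sites × 15 surveys over a
600-species flora.

## Known limitations

The classifier trusts the site reference; errors there surface as
spurious false positives (or hide real ones), and only relative
comparisons are robust to that. The true-negative convention makes
specificity's absolute level arbitrary. The D statistic's nodal-averaging
scheme is one concrete choice among the family of contrast-style
estimators; its calibration identities hold by construction, but numeric
D values from different schemes are not interchangeable, so comparisons
should use one implementation throughout. The rarity model's printed
coefficient scale depends on the occupancy units; the fit object records
them. Finally, genus-level ("cautious") signal testing requires a
convention for which tips represent a genus — results should be read as
conditional on that convention.
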