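---
title: "Models and methods in ancbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ancbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancbind)
```

`ancbind` implements the quantitative chain used to study how a
transcription factor's DNA-binding function evolves: reconstruct
ancestral protein domains on a phylogeny, measure the DNA specificity of
reconstructed proteins with protein-binding microarrays (PBMs), and
quantify affinity and kinetics for individual DNA motifs. This vignette
describes the models, the tunable parameters, the numerical choices, and
the limits of what the synthetic-data tests can show.

## Ancestral sequence reconstruction

### Model

Sequences evolve on a fixed rooted topology under the LG empirical
amino-acid substitution model with its model-defined stationary
frequencies. The rate matrix is `Q = S diag(pi)`, normalised so the
expected substitution rate at stationarity is one; branch lengths are
therefore in expected substitutions per site. Among-site rate variation
uses the discrete-gamma approximation with `k = 4` equal-probability
categories, the category rate being the category mean, and the shape
`alpha` estimable by maximum likelihood. Transition probabilities come
from one eigendecomposition of the symmetrised rate matrix
(`diag(sqrt(pi)) Q diag(1/sqrt(pi))`), which is exact for a reversible
model and numerically stable for any branch length.

Likelihoods use Felsenstein pruning with per-site, per-node rescaling,
so the same code is stable from four-taxon test trees to large
alignments. Gap and unknown characters are missing data: their tip
conditional likelihood is a vector of ones, and no column is discarded.
Reconstructed sequences consequently report a state for every alignment
column, including columns that are gapped in many extant sequences;
users who consider a column absent in an ancestor should mask it with
the posterior table in hand.

### Marginal posteriors and AltAll ancestors

Reconstruction is empirical-Bayes marginal: for each internal node and
site, the posterior distribution over the 20 states integrates over all
other nodes (an inside–outside pass over the tree) and over the rate
categories, each weighted by its site-specific posterior. The ML
sequence takes the maximum-posterior state per site; exact ties are
broken in alphabetical amino-acid order and flagged. A site is
*ambiguously reconstructed* when any non-ML state has posterior
probability strictly greater than 0.2 (the threshold is an argument).
The AltAll sequence substitutes the second-best state at all ambiguous
sites simultaneously; it represents the far edge of the plausible
cloud of ancestors, and its mean posterior probability can never exceed
the ML sequence's. The expected number of wrongly reconstructed sites
is `sum(1 - PP_ML)`.

### Optimisation

Branch lengths are optimised coordinate-wise by bounded scalar search on
`[1e-8, 20]`, with a bounded search for `alpha` interleaved, until the
log-likelihood improves by less than `1e-6` between sweeps (cap 50
sweeps, warning on hitting it). Coordinate search is slower than
gradient methods but monotone and robust, and on the problem sizes this
package targets (tens of taxa, tens to thousands of columns) it
converges in a few sweeps. Two properties matter for interpreting
results: under a reversible model the likelihood depends only on the
unrooted tree, so the two root-adjacent branch lengths are identifiable
only through their sum; and ML branch-length estimates at a few thousand
sites still carry 5–20% sampling error, which is why the package's
recovery tests simulate 8,000 columns before asserting a 15% band.

### Diagnostic substitutions

For a parent–child pair of reconstructed ancestors, the substitution
list records every differing column (labels in the conventional
lowercase-ancestral/uppercase-derived style, e.g. `q50K`). A
substitution is *phylogenetically diagnostic* when the derived state is
identical in every extant member of the designated descendant clade at
that column; a gap anywhere in the clade counts as not conserved.

## PBM specificity analysis

### E-scores

For every reverse-complement-collapsed 8-mer, the E-score is a
rank-based enrichment statistic: a Wilcoxon–Mann–Whitney comparison of
the probes containing the word (foreground) against all other probes,
computed on the most-enriched half of each set and rescaled to
`[-0.5, +0.5]`. Being rank-based it is invariant to strictly monotone
transformations of the intensities (ties are kept in stable input
order, so this holds exactly). The top-half truncation focuses the
statistic on the strong-binding tail, at a price worth knowing: under a
content-independent null the truncated statistic is not exactly centred
when foregrounds are sparse (we measure a bias near `-0.25` with
single-probe foregrounds and `-0.03` at ~15 probes per word; on
array-scale designs with >16 probes per 8-mer it is small). The
untruncated variant (`truncated = FALSE`) is exactly centred and is
what the package's null-calibration test uses. 6-mer scores are the
arithmetic mean over all scored 8-mers containing the 6-mer on either
strand, and specificity comparisons between proteins are Pearson
correlations of matched 6-mer scores.

### Clustering and logos

8-mers reaching an E-score of 0.45 in at least one construct are
clustered by complete-linkage hierarchical agglomeration on Manhattan
distances between their across-construct score profiles. For each cut
cluster the package builds a position-frequency logo by aligning member
8-mers, in both orientations and with shifts up to ±2, to a frame
anchored on the cluster's most frequent hexamer. Anchoring on the
dominant hexamer rather than on a single top-scoring word matters in
practice: E-scores saturate at +0.5 for many genuinely strong words, so
"the" top word is an arbitrary tie-break and can produce washed-out
logos.

### Energy models

The binding model is an additive position-energy matrix `eps` (motif
length L, RT units, lower = more favourable) inside a saturating
occupancy function: a window `w` of a probe contributes occupancy
`1/(1 + exp(E_w - mu))` with `E_w` the sum of its per-position
energies, and the predicted intensity is
`bg + beta * sum_w occupancy_w` over all windows on both strands.
`mu` is a chemical potential (proxy for free protein concentration),
`beta` a response scale, `bg` a background offset. Positional window
weights default to uniform.

Fitting minimises squared intensity error with analytic gradients
(L-BFGS-B). Two gauge freedoms are fixed after fitting: a constant can
move between any position's energies and `mu` (the reported matrices
are mean-centred per position), and — because both strands are scanned
— a model and its position-reversed base-complemented image predict
identically, so recovered models are compared to references after
orientation matching (`orient_energy_model()`). The objective is
non-convex: deeply unfavourable energies sit in a saturated region with
near-zero gradient, and a single optimisation run can stall there. The
fitter therefore uses a small deterministic multi-start (initial
energies scaled by 1, 1.5, 0.5) and keeps the lowest-RSS solution. Model
quality is summarised as the R² between per-8-mer median observed and
predicted intensities on a held-out replicate; because replicates differ
in overall signal strength, the default allows one linear rescaling of
the predictions (`rescale = FALSE` gives the raw version), and the
matched reproducibility ceiling is the replicate-vs-replicate R² of the
same medians. Energy logos display each base's mean-centred main effect
in RT units; favourable bases plot on the opposite side of the axis
from unfavourable ones.

## Binding quantification

### Equilibrium titrations

Bound fraction versus total protein at fixed labelled-DNA concentration
`D` follows the exact mass-action (quadratic) isotherm

```
F = b0 + (bM - b0) * [D + P + 1/KA - sqrt((D + P + 1/KA)^2 - 4 P D)] / (2 D)
```

whose bracket term avoids the free-ligand approximation; the
discriminant is floored at zero against round-off near stoichiometric
binding, and as `D -> 0` the curve reduces to the hyperbolic Langmuir
form. Fits are nonlinear least squares over `(b0, bM, log10 KA)` — the
log scale keeps `KA` positive and conditions the problem — with
standard errors from the Jacobian and a warning when the data never
leave the baselines (unconstrained `KA`). Replicates are fit
independently by default, with `KA` summarised as mean ± SEM; a pooled
mode shares all three parameters.

### SPR kinetics

The association phase of a 1:1 interaction at analyte concentration
`c0` follows

```
R(t) = kon c0 Rmax / (kon c0 + koff) * [1 - exp(-(kon c0 + koff) t)] + R_RI + cD t
```

with refractive-index jump `R_RI` and baseline drift `cD`. A single
concentration identifies only the observed rate
`kobs = kon c0 + koff`; the package offers the classical linearisation
of per-curve `kobs` against `c0` and, as the primary route, a global
fit sharing `kon`, `koff`, `Rmax` across three or more concentrations
with per-curve `R_RI` (log10-scale rates; two-stage initialisation from
the linearisation, with a fallback when `kobs` barely varies over the
concentration range). The dissociation phase — whose functional form is
the standard single-exponential companion with optional drift — is fit
separately and cross-checks `koff`. Derived quantities: `KD =
koff/kon`, residence time `tau = 1/koff`. Preference comparisons report
per-protein `KA(BM)/KA(ZM)` ratios and their across-protein shift;
equilibrium and kinetic affinity scales are never mixed silently.

## Synthetic data and the study stand-in

Every generator consumes an explicit seed and reuses the exact forward
code of the corresponding fit (`transition_prob`, `predict_intensity`,
`eval_isotherm`, `eval_association`), so simulators and estimators
cannot drift apart. PBM noise is multiplicative log-normal (default
`sd = 0.2` on the log scale) applied to the whole predicted intensity,
reflecting positive, ratio-scaled array signals; replicates get
independent noise and an optional overall scale factor, emulating the
common observation that one replicate is stronger. Titrations add
Gaussian noise to the isotherm; sensorgrams add RU-scale Gaussian noise
to both phases, with dissociation continuing from the association
endpoint.

`hd_demo_scenario()` fixes the study conditions the documentation and
acceptance checks run on: a 33-taxon rooted tree (nine outgroups, a
labelled pre-duplication ancestor whose daughters are a slow Zen-like
clade and a fast Bcd-like clade with a long stem), 60 alignment columns
under LG with `alpha = 0.8` — values chosen once as representative of a
short, conserved DNA-binding domain with strong among-site rate
variation; two energy models (TAATTA-preferring with tolerated G at
position 5 and A/G at 6 and a strong exclusion at position 2, versus
TAATCC-preferring with its own position-2 exclusion); equilibrium
truths `KA` of 1e7/1e8 (ancestral protein on BM/ZM) and 2.5e8/1e7
(derived), i.e. a 25-fold BM gain and 10-fold ZM loss whose preference
shift is 250; and kinetic truths in which the change is carried by
off-rates (66-fold slower on BM, 3-fold faster on ZM), with per-variant
injection designs bracketing each `KD` — as real SPR experiments are
designed from preliminary runs. The pipeline's energy-model stage fits
on a leading subset of probes (default 2,000) while E-scores and
clustering always use the full set; the regression's information
content saturates well before array scale and this keeps the end-to-end
demo fast.

What passing on synthetic data does and does not show: it demonstrates
that each estimator recovers the parameters of its own generating
model at realistic noise, sizes and designs, and that the full chain
propagates a planted biological signal end to end. It does not test
robustness to the things real data add — array spatial artifacts and
sequence-composition biases, non-1:1 binding, mass-transport limitation
in SPR, alignment error, or model misspecification in the substitution
process. The published summary statistics for the real study alignment
(31 ancestor-to-ancestor differences, 11 diagnostic, mean posteriors
0.970/0.986) depend on that specific alignment, which is not
redistributable here; the corresponding check therefore runs on the
synthetic stand-in and is expected to disagree with the printed values
— it documents the gap rather than papering over it.

## Numerical choices, in one place

* Transition probabilities: eigendecomposition in the
  square-root-frequency basis; negative round-off clipped, rows
  renormalised.
* Pruning: per-site, per-node log-scale accumulation; categories
  combined by log-sum-exp.
* Branch-length bounds `[1e-8, 20]`; shape bounds `[0.02, 100]`;
  convergence `delta lnL < 1e-6`.
* ML-state ties: alphabetical, reported in `tied_sites`.
* Ambiguity threshold: strict `> 0.2` on the best non-ML state.
* E-score ties: stable first-occurrence order (preserves monotone
  invariance); truncation `ceiling(n/2)` of each set.
* Energy fit: L-BFGS-B, analytic gradients, energies bounded at ±30 RT,
  deterministic multi-start, mean-centred gauge, orientation fixed
  against a reference only when one is supplied.
* Isotherm: discriminant floored at 0; `KA` on log10 scale.
* Kinetics: rates on log10 scale; `koff` lower bound flagged when hit;
  dissociation requires a detectable decay.

## Known limitations

Marginal (not joint) reconstruction only; no topology search or branch
supports; amino-acid models only. E-scores use the package's own
truncated-WMW definition — the original array-analysis suite's exact
truncation and tie rules are not published, so small numerical
differences from its output are expected (hence the configuration
switch). Energy models are strictly additive per position
(mononucleotide); no dinucleotide terms. SPR modelling assumes 1:1
Langmuir binding without mass-transport terms. The pipeline's report is
plain text plus JSON; figure generation is limited to a base-graphics
energy-logo renderer.
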