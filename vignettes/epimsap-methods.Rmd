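---
title: "Methods: MSAP scoring, epigenetic differentiation, and transgenerational stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSAP scoring, epigenetic differentiation, and transgenerational stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Methylation-sensitive amplified polymorphism (MSAP) profiles anonymous
5'-CCGG sites genome-wide by running an AFLP protocol twice per sample, once
with each of the isoschizomers *Hpa*II and *Msp*I. The two enzymes recognise
the same tetranucleotide but differ in their sensitivity to methylation of
the inner and outer cytosine, so the band-presence pattern of a fragment
across the two products encodes its methylation state:

* band in **both** products — the site is non-methylated (state 0);
* band in **exactly one** product — hemimethylation or internal-cytosine
  methylation (state 1);
* band in **neither** product — uninformative: either the fragment is
  genotypically absent or the site is hypermethylated (scored missing).

`epimsap` treats the methylated state as an imperfectly assessed dominant
marker, and provides the full analysis chain for a paired
sporophyte–gametophyte design: the same individuals are sampled as adult
plants (leaf DNA) and as their descendant male gametophytes (pollen DNA),
so that changes in methylation across male gametogenesis can be read
locus-by-locus within individuals.

# Scoring (`score_msap`)

1. **Size filter.** Fragments shorter than `min_bp` (default 150 bp) are
   dropped to limit size homoplasy.
2. **Error estimation** (`estimate_error_rates`). A subset of samples
   (default 30%) is scored twice; a fragment's error rate is the proportion
   of discordant scores between the two analyses. Discordances are pooled
   over the two enzyme arms by default, so the denominator for a fragment is
   `2 * n_replicates`; per-arm estimation is available. Fragments with no
   replicate coverage are flagged and excluded from the median.
3. **Error filter** (`filter_fragments_by_error`). Only fragments with an
   error rate strictly below the median of the whole error distribution are
   retained. Strictness matters only for ties at the median; both the strict
   (default) and non-strict rules are available. Because the same noisy
   estimate is used for selection and for the retained-set mean, the
   reported mean error of retained fragments is slightly optimistic
   (winner's curse); this mirrors how such filtered error rates are usually
   reported.
4. **Locus classification** (`classify_loci`). A fragment is
   *methylation-susceptible* (MS) when its observed *Hpa*II/*Msp*I
   discordance proportion exceeds what scoring error alone could produce.
   The threshold is derived from the combination's mean retained error rate
   `e`: a spurious mismatch needs at least one of the two independent scores
   to err, giving `1 - (1 - e)^2` (the default `"compound"` rule). Since the
   measured `e` is itself a two-scoring discordance rate, this threshold is
   intentionally conservative — roughly twice the true error-only mismatch
   probability. The plain rule (`e` itself) and a median-based combination
   summary are provided because the field's usage is not standardised.
5. **Methylation scoring** (`score_methylation`). The three-condition rule
   above, applied cell-wise; the result is a samples × MS-loci matrix over
   {0, 1, NA}.

# Differentiation among sites (`differentiate_msap`)

**Single locus.** For each polymorphic MS locus, a site × state contingency
table of informative scores is tested with Fisher's exact test
(probability-ordering two-sided convention; for three sites this is the
2 × 3 exact test). False discovery rates are controlled with Storey
q-values: `pi0` is estimated by the smoother method (cubic smoothing spline
of `pi0(lambda)` over `lambda = 0.05 ... 0.95`, evaluated at 0.95), and
q-values are step-up monotone; with fewer than 10 tests `pi0` is fixed at 1,
which reduces q-values exactly to Benjamini–Hochberg. A locus is declared
significant only when both p < 0.05 and q < 0.05.

**Multilocus.** Pairwise distances between samples are squared Euclidean
distances between score vectors, with missing data handled by proportional
rescaling: `d(i,j) = (L / L_ij) * sum_shared (x_i - x_j)^2`, where `L_ij`
counts loci informative in both samples. A pair sharing no informative locus
is a hard error (such data cannot be placed in the distance space). A
one-level AMOVA partitions the squared distances into among- and
within-site components via the standard sums-of-squares decomposition;
`Phi_st = sigma2_among / (sigma2_among + sigma2_within)` and its
significance comes from permuting site labels
(`p = (1 + #{Phi_perm >= Phi_obs}) / (1 + n_perm)`, default 9999
permutations, seed mandatory). Pairwise `Phi_st` re-runs the AMOVA on each
site pair. Ordination uses Kruskal's nonmetric MDS (`MASS::isoMDS`) on the
square-rooted distances, best of 20 restarts (classical-scaling start plus
random starts), stress-1 reported on the 0–1 scale. Zero distances between
identical epigenotypes are nudged to a tiny positive value, as the isotonic
fit requires positive dissimilarities; note that NMDS preserves only rank
order, so coincident samples are guaranteed to be *closest*, not coincident,
in the configuration.

A locus is counted polymorphic when both states occur among its informative
scores; a minority-frequency cutoff (e.g. 5%) is available because with
60 samples and ~4% scoring error essentially every locus shows both states
at least once, which inflates the zero-cutoff percentage to near 100%.

# The sporophyte-to-gametophyte stage (`transgen_msap`)

**Change table.** Each (individual, locus) pair is compared between
generations. Both states missing: the comparison is discarded. Exactly one
missing: the informative partner proves the individual carries the fragment,
so the double band absence on the other side cannot be genotypic absence —
it is read as hypermethylation and resolved to the methylated state
(`resolve = "hypermethylation"`, the default). The alternative reading
(copy the partner's state, so such comparisons never register a change) is
available as `resolve = "copy"` for sensitivity analysis.

**Summaries.** The overall change rate is changes / retained comparisons;
direction shares are computed over changes only. Per-locus instability is
the proportion of individuals (all sites combined) whose state changed, with
an exact Clopper–Pearson 95% interval and the `asin(sqrt(p))`
variance-stabilising transform.

**Bimodality and stability classes.** Unimodality of the arcsin-transformed
instabilities is tested with the Hartigan–Hartigan dip statistic. The dip is
the smallest sup-norm distance between the empirical CDF and any unimodal
CDF (convex below its mode, concave above, an atom allowed at the mode). The
implementation minimises, over candidate modes at the data points, the
minimal half-width of the ECDF band admitting a convex/concave interpolant
on either side; modes between data points never improve on this (bending at
the neighbouring point costs no more), so the statistic is exact. The
p-value is Monte-Carlo against uniform samples of the same size (default
2000 replicates) — the uniform is the least-favourable unimodal null, so the
test is conservative for peaked unimodal alternatives. After bimodality is
established, loci are classified into `stable` / `unstable` by a
two-component Gaussian mixture on the arcsin values fitted by EM
(\pkg{mclust}; equal- and unequal-variance models compared by BIC, lower
mean = stable, degenerate fits retried from jittered data up to 10 times).

**Change-probability model.** The probability that a single comparison
registers a change is modelled as `change ~ site + locus`, a fixed-effects
binomial GLM with logit link fitted to the retained comparisons (aggregated
to site × locus counts, which is likelihood-equivalent). Site and locus
effects are tested by likelihood-ratio chi-square tests; this replaces the
pseudolikelihood F-tests with containment degrees of freedom that
SAS-GLIMMIX-style analyses report, a tool-specific convention that cannot be
reproduced exactly elsewhere. Per-site probabilities are inverse-logit site
estimates averaged over loci on the link scale with delta-method standard
errors (\pkg{emmeans}). Averaging on the link scale means these
probabilities sit below the raw per-site comparison rates (a geometric-type
mean over very heterogeneous loci); per-locus back-transformed change
probabilities can be orders of magnitude below the raw rate, so the
response-scale per-site values reported here are the interpretable
quantity. A locus whose comparisons are all changes or all non-changes is
completely separated; it receives a half-success/half-failure pseudo-count
(a weak ridge) and is flagged.

Per-individual change proportions are compared across sites with the
Kruskal–Wallis rank-sum test (tie-corrected H, chi-square reference on
k − 1 df).

**Joint ordination.** The loci with significant site differentiation in
either generation (union set) are used to build one distance matrix over all
2n samples; a common NMDS places sporophytes and gametophytes in one space,
and per-individual displacement vectors (gametophyte minus sporophyte
coordinates) quantify multilocus reorganisation. On the same locus subset
the package reports the gametophyte-stage AMOVA and the Mantel correlation
(10 000-permutation default) between the sporophyte and gametophyte distance
matrices.

# The synthetic-data generator (`sim_config`, `simulate_msap`)

The generator emulates a three-site, 20-individuals-per-site, two-generation
MSAP study with four primer combinations. Its defaults are the study
conditions the package is validated against:

| parameter | default | meaning |
|---|---|---|
| `locus_allocation` | 36/44/47/16 | retained loci per combination (total 143) |
| `ms_allocation` | 22/37/36/12 | retained MS loci per combination (total 107) |
| `error_rates` | 4.1/4.2/4.6/5.2% | mean scoring error of retained fragments |
| `target_phist` | 0.30 | measured multilocus sporophyte Phi-st |
| `change_rates` | 0.137/0.180/0.162 (TEJ/NAV/PLL) | measured per-site change rates |
| `direction_bias` | 0.803 | measured share of changes going 0 → 1 |
| `stable_fraction` | 0.748 | fraction of MS loci in the stable class |
| `hyper_prob` | 0.15 | P(double absence \| methylated), per generation |
| `fragment_absence` | 0.12 | P(genotypic fragment absence) at MS loci |
| `replicate_fraction` | 0.30 | samples re-scored for error estimation |

Model structure:

* **Fragments.** Twice the target allocation is rendered per combination
  (the below-median error filter removes about half), plus a few undersized
  fragments to exercise the size filter. Per-fragment error rates follow a
  lognormal whose location is set so the retained half averages the
  configured rate; the per-scoring flip probability `f` solves
  `2 f (1 - f) = rate`, because the configured rate is a
  two-independent-scorings discordance.
* **Sporophytes.** MS loci are either variable (baseline frequency uniform
  on 0.15–0.85; fraction 0.45) or near-fixed methylated (0.95). Site
  differentiation enters as logit-scale offsets `tau * z_ls` at stable MS
  loci; `tau` is calibrated (below). States are independent Bernoulli draws
  per individual and locus — the generator has no linkage or spatial
  autocorrelation, a deliberate simplification.
* **Gametogenesis.** A cell in state 0 changes with probability
  `c * b / (1 - p)` and a cell in state 1 with `c * (1 - b) / p`, where
  `c` is the latent site rate times the locus-class multiplier and `p` the
  locus's site-level frequency; this preserves both the class-specific rate
  and the direction bias `b` in expectation. Unstable loci (multiplier 3.7,
  stable multiplier ~0.09) are drawn among low-frequency polymorphic loci
  (baseline ≤ 0.35) and carry no site offsets — otherwise the strongly
  up-biased process hits the per-cell probability cap at high-frequency
  sites, which smears the unstable instability mode and destroys the
  bimodality the two-class model is meant to produce. With these defaults
  the stable mode sits near the scoring-artifact floor (~0.06) and the
  unstable mode near 0.4, and the dip test rejects unimodality in most
  datasets.
* **Rendering.** State 0 → both bands; state 1 → one band (arm uniform);
  hypermethylated or genotypically absent → no band. Independent per-cell
  bit flips at the fragment's flip rate produce the observed matrices, and a
  30% sample subset is re-flipped as replicates.

**Calibration.** The configured `target_phist`, `change_rates` and
`direction_bias` are *measured* quantities: they are what the noisy scoring
pipeline reports, not latent process parameters. Scoring error alone
produces ~5% apparent, direction-symmetric changes, so a latent process set
naively to the targets would overshoot the measured rate and undershoot the
measured bias. `calibrate_generator()` therefore (1) bisects `tau` until the
mean pipeline-measured sporophyte Phi-st over 8 simulated datasets hits the
target within 0.02 (an unattainable target errors out with the attainable
range), and (2) runs a five-step fixed-point iteration on the latent
per-site rates and latent bias until the measured per-site rates and
direction share match their targets (the final iterations use 24 datasets,
holding the residual per-site error below ~0.004). Calibration is
deterministic given the configuration seed and cached within the session.

**What passing tests do and do not show.** The generator reproduces the
study's marginal structure — locus counts, error rates, missingness,
site-differentiated frequencies, a bimodal two-class change process with the
configured rate and direction bias — so end-to-end recovery of those
parameters validates the estimators under realistic noise. It does not
emulate linkage between loci, site-specific error, pollen-specific artefacts
(e.g. methylation differences between vegetative and sperm nuclei), or any
sequence-level mechanism, so passing tests say nothing about those failure
modes on real data.

One consequence of honest measurement noise is worth stating explicitly:
with per-site rate gaps of ~0.02 and ~1850 retained comparisons per site,
the sampling SD of a measured site rate is ~0.012–0.015 per dataset, so the
full ordering of the three site rates is recovered in only ~75–85% of
simulated studies. That is a property of the design, not of the estimators —
ordering measured on the true change events (no scoring noise) is recovered
in >99% of datasets.

# Numerical choices and degenerate inputs

* Permutation and Monte-Carlo p-values always use add-one smoothing and an
  explicit seed; all generator randomness flows through seeds derived from
  the configuration seed.
* Distance rescaling errors out (naming the pair) when two samples share no
  informative locus; the pipeline skips the union-locus cross-generation
  analyses with a warning when the restricted locus set is too sparse.
* Monomorphic loci get Fisher p = 1 and are flagged; a locus with zero
  retained comparisons is dropped from the instability profile with a
  warning; an all-identical instability vector yields the minimal dip
  `1/(2n)` with p = 1; a degenerate Kruskal–Wallis (all proportions equal)
  reports H = 0, p = 1, flagged.
* The dip implementation is O(u³) in the number of unique values (compiled);
  the test suite checks it against an algorithmically independent
  constructive feasibility oracle.

# Problem sizes used in validation

The test suite validates estimators on small instances (oracle equivalence
at n ≤ 24 samples), checks type-I error at 250–400 simulation replicates,
and runs end-to-end parameter recovery on 40 generator datasets at the
default study size; the acceptance script analyses one full dataset with
9999 permutations. These sizes were chosen so the whole suite completes in a
few minutes on one core while keeping Monte-Carlo error well inside the
asserted tolerances.

# Known limitations

* Loci are generated and analysed as independent; the AMOVA treats the
  multilocus vector jointly but no linkage model is provided.
* The q-value smoother needs a healthy p-value set; below 10 tests it falls
  back to Benjamini–Hochberg.
* Female gametogenesis is out of scope (the paired design covers pollen
  only), as are electropherogram processing and fragment calling — inputs
  are presence/absence matrices.
* The reported mean error rate of retained fragments is selection-biased
  low relative to the true error of those fragments (see Scoring, step 3).
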