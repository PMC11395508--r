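---
title: "Scoring gut dysbiosis with a stratified-reference quadratic dissimilarity index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gut dysbiosis with a stratified-reference quadratic dissimilarity index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdikit)
```

## The model

A gut microbiota profile is a point on the probability simplex: relative
abundances of taxa summing to 1. `mdikit` scores a patient by the quadratic
dissimilarity between their profile and a matched healthy reference profile,

$$Z = \sqrt{\tfrac{1}{2}\sum_t \left(f_{case,t} - f_{control,t}\right)^2},$$

evaluated independently at the phylum, family and genus ranks and averaged
(unweighted) into the microbial dysbiosis index, MDI $= 100\bar Z$ percent.
The $\tfrac12$ factor gives the index its endpoints: identical profiles give
0; profiles with disjoint support concentrated on single taxa give exactly 1;
and for any two simplex points $\sum_t(a_t-b_t)^2 \le \sum a_t^2 + \sum b_t^2
\le \sum a_t + \sum b_t = 2$, so $Z \le 1$ always. Both endpoint identities
and the bound are property-tested over random simplex draws.

Two structural decisions deserve comment:

* **Per-rank, then average.** A single sum running jointly over all three
  ranks would operate on a vector summing to 3 and could reach
  $\sqrt{3} \approx 1.73$, breaking the $[0,1]$ interpretation. Computing
  $Z$ per rank and averaging preserves the bound and weights the ranks
  equally; no evidence known to us motivates unequal weights.
* **Union alignment.** Case and reference vectors are aligned on the union
  of their taxa; a taxon present on only one side contributes its full
  squared abundance. This is what makes the disjoint-support endpoint
  attainable and penalises colonisation by taxa absent from healthy guts.

Profiles are built per subject: each sample column is converted to relative
abundances after rank collapse; a subject with several samples contributes
the per-taxon **median** across their samples, renormalised to sum 1
(coordinate-wise medians do not generally lie on the simplex; without
renormalisation the index bound would be lost).

## The stratified healthy reference

The reference for a patient is the per-taxon median profile of healthy
controls in the matching (age bin, gender) stratum, again renormalised per
rank. Age bins default to the paediatric grid 0–4, 4–11, 11–19 years —
chosen to split infancy/weaning, childhood, and adolescence, the periods
with distinct microbiota maturation — and are fully configurable.

A stratum with fewer than `min_controls` (default 5; medians over fewer
profiles are dominated by individual controls) falls back along a cascade,
re-medianing over progressively wider pools: (1) both genders within the
age bin, (2) the adjacent age bins, (3) all controls. The fallback level is
recorded in each result's provenance so downstream analyses can see which
comparisons used a thinner reference. Reference sets serialise to JSON,
including the contributing control profiles (the cascade needs them), so a
fixed reference can ship with a deployment.

## Preprocessing

* **Prevalence/abundance filter.** A taxon is retained iff its relative
  abundance reaches at least `min_ra` (default 0.01) in at least a
  `min_prevalence` fraction of samples (default 0.25), both boundaries
  inclusive. The common English phrasing of this rule ("present in less
  than 25% of samples with relative abundance < 0.01") is ambiguous between
  a conjunction and a nested condition; we read *presence* as "abundance at
  or above the 1% level" and apply the prevalence threshold to that
  presence. The filter is idempotent.
* **CSS normalisation.** Counts are divided by the sample-specific sum of
  counts up to a quantile of the nonzero-count distribution (default 0.5),
  times a common scale (default 1000). The adaptive quantile search of the
  original CSS method is replaced by a fixed configurable percentile:
  deterministic, testable, and adequate for correlation analyses, which are
  invariant to per-sample monotone scaling errors far smaller than the
  biological signal.
* **Rarefaction.** Without-replacement subsampling (hypergeometric) of each
  sample to a common depth via `vegan::rrarefy`, seed-controlled; samples
  below depth are dropped with a warning or abort the run, per
  configuration. Used for the diversity branch only.

The default pipeline order is: genus collapse → filter → three branches
(rarefaction for diversity, relative abundance for the MDI, CSS for the
correlation battery). Whether the filter precedes or follows normalisation
is exposed rather than hard-coded — the branches each start from the
filtered count table.

## The association battery

Taxa–MDI associations use Pearson's product-moment correlation (Spearman
for the faecal–ileal network), two-sided p-values, and Benjamini–Hochberg
q-values with one correction family per niche per run. Coefficients are
banded on $|\rho|$ with right-closed boundaries: weak $\le 0.3$, moderate
$\le 0.7$, strong $> 0.7$. (Verbal conventions in the literature sometimes
call coefficients near 0.6 "strong"; the package applies the stated numeric
rule.) Constant features are excluded with a warning, never silently
assigned $\rho = 0$. Group comparisons use the Mann–Whitney U test for two
groups (exact for small untied samples, normal approximation with tie
correction otherwise) and Kruskal–Wallis beyond that; PERMANOVA uses
Anderson's pseudo-F with the +1-corrected permutation p-value, so p can
never be 0 and the smallest attainable value is $1/(n_{perm}+1)$.

Shannon diversity uses the natural logarithm by default, with the base
exposed (`base = 2` reproduces the common QIIME convention). Chao1 uses the
classic estimator $S + F_1^2/(2F_2)$ with the bias-corrected branch
$S + F_1(F_1-1)/2$ when no doubletons exist; this differs from the
always-bias-corrected variant in `vegan::estimateR`, which is why the
estimator is implemented directly.

## The synthetic cohort generator

The generator exists so every operation — including the full pipeline — can
be exercised and calibrated without sequencing data. Subject communities
are drawn Dirichlet(concentration × mean) over a fixed 40-genus catalogue
with Greengenes-style lineages, then observed as multinomial reads at the
configured depth (default 10,000). The concentration default of 50 gives
between-subject overdispersion of the magnitude seen in real 16S cohorts
(taxon CVs of roughly 15–40% for dominant genera).

The dysbiosis axis moves a mass `effect` from the protective commensals to
pro-inflammatory taxa, proportionally to baseline weight within each set.
The catalogue's healthy community is dominated by two protective genera —
*Faecalibacterium* (0.29 of the community) and *Bacteroides* (0.20) — and
the enriched set is an Enterobacteriaceae bloom (*Escherichia*,
*Klebsiella*, *Enterobacter*). This concentration is deliberate: it mirrors
the canonical severe-IBD signature (loss of dominant butyrate producers,
proteobacterial bloom), and a shift diffused over many minor taxa cannot
produce high-grade dissimilarity — squared deviations shrink quadratically
as the same mass is split — leaving the >35% class empty under any
realistic effect. With the concentrated axis the index responds at roughly
0.85 percentage points per percentage point of shifted mass, and effects of
0.08/0.33/0.48 land the class centres near 12%/30%/45%.

Per-case effects are drawn Uniform(0, `effect_size`) so one cohort spans
the whole severity range; clinical activity scores follow
$a + b\,\mathrm{effect} + \mathcal N(0, sd)$ clipped to the instrument
range (PUCAI for UC, PCDAI for CD); marker levels (urinary indican, faecal
zonulin, secretory IgA) are lognormal with means/SDs matching published IBD
cohort values. `emulate_ibd_cohort()` fixes the margins of a 35-patient
paediatric cohort (14 UC / 21 CD, 18 male / 17 female, 11 active / 24 in
remission, localisation 4/3/4/9/15) with a 50-control pool and the three
frozen effect levels above.

What the generator does **not** emulate: real lineage uncertainty and
unclassified reads, sample-to-sample sequencing-depth variation, strain
level dynamics, compositional correlations beyond the Dirichlet (e.g.
cross-feeding guilds), and any longitudinal structure. Passing tests
therefore demonstrate the correctness and calibration of the *procedures*,
not the clinical accuracy of the index on real cohorts.

## Calibration experiments and problem sizes

The test suite runs the statistical checks at these sizes, chosen to give
the stated precision at interactive runtimes:

* Index bound/symmetry: 10,000 random simplex pairs (2–40 taxa).
* FDR: equivalence with a brute-force step-up oracle on 1,000 random
  p-vectors of length ≤ 20; Mann–Whitney against exhaustive enumeration of
  all 20 rank assignments at $n = 3,3$.
* PERMANOVA size: 200 replicate null datasets (20 samples, 15 taxa, two
  groups of 10, 199 permutations); empirical rejection at $\alpha = 0.05$
  required within $0.05 \pm 0.03$.
* Parameter recovery: Pearson correlation between injected effect and
  computed MDI pooled over five cohorts of 50 cases (depth 10,000, effects
  Uniform(0, 0.3), 100-control reference pool) required $\ge 0.8$; a single
  50-case cohort estimates this correlation with a standard error near
  0.045, so pooling is used to test the property rather than the sampling
  noise of one draw. Mean MDI must increase strictly over the effect grid
  0/0.1/0.2/0.3 at 50 cases per point.
* Null calibration: with zero effect, the taxa–MDI battery flags 5% ± 3% of
  taxa at $\alpha = 0.05$ pre-FDR, pooled over five cohorts (200 tests).
* Determinism: the emulated cohort through the full pipeline twice under
  one seed produces byte-identical artifacts.

## Numerical choices and degenerate inputs

Simplex sums are validated to $10^{-9}$ on I/O and $10^{-6}$ inside the
dissimilarity (profiles that have been medianed and renormalised accumulate
rounding). All-zero samples are never silently normalised: relative
conversion leaves them zero and warns, CSS refuses them by name, and
all-zero abundance vectors are errors in the index and diversity functions.
Missing metadata values stay missing (`NA`), never 0. Class boundaries are
assigned with 25 and 35 both falling to "moderate". Percentages are
reported to one decimal with half-away-from-zero rounding; a 19/35 share
therefore prints as 54.3. Every stochastic step (rarefaction, PERMANOVA,
generation) takes an explicit seed and restores the caller's RNG state.

## Limitations

The index compares against medians of whatever controls are supplied; it is
only as good as the reference pool, and the fallback cascade trades
matching fidelity for stability in thin strata. Quadratic dissimilarity is
dominated by abundant taxa — a complete loss of a 0.5%-abundance genus
moves the index by at most ~0.4 points — so it is a measure of
community-scale displacement, not of rare-taxon pathology. Bray–Curtis is
not a metric and the PERMANOVA wrapper inherits its sensitivity to
dispersion differences between groups. The generator's Dirichlet model has
no taxon–taxon correlation structure beyond compositionality.
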