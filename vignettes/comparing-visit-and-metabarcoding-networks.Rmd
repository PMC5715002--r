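---
title: "Comparing visit-survey and pollen-metabarcoding pollination networks"
author: "pollinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing visit-survey and pollen-metabarcoding pollination networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollinet)
```

## The problem

A pollination network is a bipartite graph between plant taxa and their
insect visitors. Classically it is built phytocentrically: observers watch
flowers and record visits, and the matrix cell a_ij is 1 when insect j was
seen on plant i. This undersamples rare interactions severely — rare
species look like specialists simply because they are rarely watched.

Pollen DNA metabarcoding inverts the viewpoint: each captured insect's
pollen load is sequenced, and taxa identified in the load testify to the
plants the insect actually contacted, across its whole recent foraging
history and across a wider area than the surveyed plots. The price is a
different error structure: background contamination (chiefly airborne
pollen of wind-pollinated grasses), carryover of small amounts of pollen,
and an effective sampling effort so much larger than a visit survey's that
nearly every size-sensitive network index shifts for reasons that have
nothing to do with biology.

`pollinet` implements the complete chain needed to compare the two data
streams honestly: thresholded interaction calling, network construction at
three resolution levels, a full index suite computed from first
principles, fixed-marginal null models, and a size- and effort-matched
rarefaction test.

## Interaction calling

A link is called when an insect's pollen load contains **strictly more
than** `threshold` reads of a plant taxon (default 1,000; when separate
marker tables, e.g. *trnL* and ITS1, are supplied, either marker may
exceed the threshold on its own — counts are never summed across
markers). Before thresholding, wind-pollinated taxa (the contamination
background itself) and taxa only resolvable above genus level are
discarded; genus-rank taxa are kept as genus nodes. Insects left with no
super-threshold taxon are dropped, as are plants linked to no insect, so
constructed matrices never contain empty rows or columns — an invariant
enforced by the `InteractionMatrix` class validity.

The threshold's rationale is empirical: grasses blanket the study system
with low-level airborne background (in the emulated profile, 65% of
insects carry some grass reads but only 11.5% carry more than 1,000),
so a count high above that background is taken as proof of a visit.
`contaminationProfile()` reports the observable side of this argument and
`thresholdSensitivity()` the consequence of halving/doubling the
threshold; the number of links is non-increasing in the threshold by
construction.

## The index suite

All indices are computed from the plant × pollinator matrix
M = [a_ij]_(P×A) with row totals r_i, column totals d_j and grand total F.

* **Counts and ratios.** Links I (nonzero cells), connectance
  C = I/(A·P), interaction density I/(A+P), mean linkage levels I/P and
  I/A, and extreme specialization (the percentage of species with exactly
  one partner).
* **Nestedness temperature.** The classic calculator is notoriously
  under-specified, so the convention here is fully documented and
  validated by limit cases rather than by value-matching published
  numbers: rows and columns are packed by decreasing marginal totals
  (ties broken lexicographically by label); cells map into the unit
  square; the isocline of perfect nestedness is the member of the family
  y = (1 − x^p)^(1/p) whose enclosed area equals the fill; the
  unexpectedness of a presence above the isocline (or absence below it)
  is its distance to the isocline along the cell's diagonal, normalized
  by the diagonal's length; T = 100·mean(u²)/0.04145, clamped to
  [0, 100]. Perfectly nested staircases score near T = 0; checkerboards
  land in the hot end of their fixed-marginal class (exhaustively
  enumerated in the tests). Degenerate single-row/column matrices take
  T = 0 by convention.
* **Barber bipartite modularity.** Q = (1/F) Σ_ij (a_ij − k_i d_j/F)
  δ(g_i, g_j), maximized by weighted label propagation alternating
  between the two node sets, followed by agglomerative merging of module
  pairs whose merge does not decrease Q, restarted from seeded random
  partitions (20 restarts for headline numbers, fewer inside
  null/rarefaction replicates). The stochastic search is deterministic
  under the seed; two equal complete blocks recover Q = 1/2 exactly, and
  a complete bipartite matrix collapses to one module with Q = 0.
* **H2′ and d′.** H2 = −Σ p_ij ln p_ij with p_ij = a_ij/F;
  H2′ = (H2max − H2)/(H2max − H2min) where the extremal entropies are
  taken over integer matrices with the observed marginals. The extremes
  come from greedy fills (largest-remainder rounding toward independence
  for the maximum; concentrate-largest-marginals for the minimum),
  refined by an exhaustive 2×2-swap local search on matrices of at most
  120 cells — on the enumerable fixtures in the tests this reproduces
  the true extremes exactly; on large matrices the greedy fill alone is
  used for speed and H2max/H2min are clamped around the observed H2 so
  H2′ always stays in [0, 1]. Species-level d′ is the Kullback–Leibler
  divergence of a species' interaction profile from partner availability
  q_j = d_j/F, standardized by the analytic extremes given the
  marginals: d_min = 0 (divergence is non-negative and attained by an
  availability-matching profile) and d_max from allocating the species'
  total to partners in order of increasing availability, capped by the
  partners' own totals.
* **Evenness.** E2 = H2″/Hmax with Hmax = ln(A·P), the all-cells
  convention under which only the full uniform matrix reaches 1.
* **Connectivity pattern.** The cumulative distribution P(k ≥ s) over
  distinct degrees is fitted by nonlinear least squares to exp(−s/γ),
  s^(−γ) and s^(−γ)·exp(−s/k_x); models are ranked by Gaussian AIC, and
  at least five distinct degree values are required. The links-per-species
  versus interaction-frequency relation is fitted by OLS on log10–log10
  axes — the slope magnitudes (< 1 on data spanning orders of magnitude)
  only make sense on a log–log scale, which we adopt as a convention.

## Null models and the rarefaction comparison

Whether an index reflects ecological structure is judged against 100
random matrices with exactly the observed row and column totals
(Patefield's algorithm, via `stats::r2dtable`), so null networks keep
common and rare species alike. The 95% CI is the empirical 2.5–97.5
percentile interval (a normal-approximation CI is available behind the
`ciType` switch; the percentile form is the default because nothing
guarantees symmetric null distributions). An index strictly outside its
CI is starred. Note the finite-ensemble caveat: CI-exclusion from 100
replicates rejects a true null at roughly 7–8%, not the nominal 5%, an
inherent property of empirical percentile envelopes that the calibration
test documents.

Because N_seq is bigger and denser than N_obs for reasons of sampling
effort alone, raw index differences are uninterpretable. The comparison
therefore (1) restricts both matrices to the species present in both
(rows/columns emptied by the restriction are dropped from both sides),
(2) draws 1,000 multinomial downsamplings of the restricted N_seq at the
restricted N_obs interaction total, with cell probabilities a_ij/F, and
(3) computes every index — including the frequency–connectivity slopes —
on each rarefied matrix, after dropping rows/columns emptied by chance
and recomputing A and P per replicate. The empirical p-value uses the
add-one estimator (1 + #more-extreme)/(n + 1) on the smaller tail (the
"above or below" proportion folded to two-sided form; the direction is
stored alongside), so p = 0 is impossible and p ∈ (0, 1] by
construction. Bonferroni correction runs over the indices of one
comparison table. A practical floor follows: with 17 indices the
adjusted p can only clear 0.05 if the replicate count exceeds 340 —
hence the 1,000-draw default.

## The synthetic world

No interaction matrices are distributed with the package; scenarios are
generated from a known ground truth so every claim a test makes can be
checked against the generating process.

* **Community.** Defaults: 60 insect-pollinated plant taxa, 80 insect
  species, 402 captured individuals. Plant abundances follow a lognormal
  rank-abundance curve (sdlog 1.5) — few common, many rare taxa; insect
  species abundances likewise (sdlog 1.2). A third of plant taxa grow
  off-site: reachable by foraging insects, hence present in pollen loads,
  but never recorded by the on-site visit survey. Taxa only resolvable
  above genus (5% by default) are placed in the off-site pool — they can
  only surface via sequencing, and the calling step discards them.
* **Preferences.** Each of the nine pollinator groups carries a
  propensity vector over the four floral morph groups (zygomorphic,
  tubular, ligulate, actinomorphic); the propensity sets the realized
  morph share and abundance distributes it within a morph, so a bee
  propensity of 0.86 on zygomorphic flowers yields an 0.86 zygomorphic
  visit share in expectation. Default group shares put Empididae (24%)
  and Syrphidae (20%) ahead, with bumblebees at 26%.
* **Pollen accumulation.** One recorded capture visit per individual
  (capture-on-flower design; multi-observation surveys are out of scope).
  The latent foraging history has zero-truncated-Poisson length with mean
  4 and ends in the capture visit; each visited plant leaves a
  super-threshold read count (lognormal shifted above the threshold) with
  probability 1 − carryoverRate (default 0.1), otherwise a sub-threshold
  geometric count. Only the side of the threshold matters downstream, so
  the exact read-count laws are convenience choices. The mean history
  length of 4 drives the roughly fourfold link inflation of N_seq over
  N_obs.
* **Contamination.** 35% of insects carry no grass reads; contaminated
  insects draw a lognormal total with meanlog 5.159 and sdlog 1.887 —
  the two parameters solving P(total < 100 | contaminated) = 0.385 and
  P(total > 1000 | contaminated) = 0.177, so the marginal profile is
  35% zero / 60% below 100 / 11.5% above 1,000. Totals are split across
  five grass taxa with a strongly skewed weight vector. The *fraction of
  grass read mass* removed by thresholding is deliberately not
  calibrated: under a heavy-tailed total-count law most read mass sits in
  few super-threshold cells, so the removed-mass fraction is sensitive to
  tail shape in a way the three insect-fraction parameters are not.
* **What a green test does not establish.** The generator reproduces the
  stated contamination profile, the capture design and the qualitative
  link inflation — not the published index values, which depend on the
  real community's structure. Tests against the generator validate the
  machinery (calling, aggregation, indices, nulls, rarefaction), while
  the published data-dependent values (H2′ = 0.47, modularity = 0.44,
  regression slopes, null CIs) are unreachable without the undeposited
  field matrices and are covered by property-based checks instead.

With contamination off, carryover 0 and single-visit histories, the
sequence pipeline reduces exactly to the visit pipeline — the end-to-end
identity the test suite asserts bit-for-bit.

## Numerical choices and degenerate inputs

* "More than 1,000 sequences" is strict inequality; 1,000 reads is not a
  link, 1,001 is (boundary-tested).
* All randomness funnels through one seeded generator per stage; a
  scenario seed reproduces visits, pollen loads, null ensembles and
  rarefactions byte-for-byte.
* Empirical CIs use quantile type 7; significance requires the observed
  value strictly outside the interval, so marginal-determined indices
  (A, P, size) can never be starred.
* Single-row or single-column matrices are forced under fixed marginals:
  Patefield resampling returns them unchanged, and their temperature is
  0 by convention.
* Rarefied replicates on which an index fails (e.g. a degenerate
  regression) are excluded for that index with a warning rather than
  failing the run.

## Limitations

* Sequence-level processes (PCR error, chimeras, taxonomic assignment)
  are out of scope; the generator emits the post-bioinformatics count
  table directly, and read counts are treated as evidence for presence
  only, never as quantitative interaction strength.
* The nestedness temperature follows this package's documented
  convention; absolute values are comparable within the package, not
  across calculators (the tests check rank agreement with an independent
  implementation, and limit cases).
* The modularity search is a heuristic; restarts make the reported Q a
  lower bound on the optimum, tight on small community-scale matrices.
* Group-level and per-species individual networks are built and
  described but not rarefaction-tested — the size-matched comparison is
  defined for the species × species pair only.
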