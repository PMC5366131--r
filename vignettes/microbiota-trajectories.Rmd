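---
title: "Longitudinal microbiota trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal microbiota trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbtraj)
```

mbtraj analyses dense per-subject gut-microbiota time series from small,
closed cohorts — the kind collected when a handful of people share a
confined habitat for many months and sample their stool repeatedly before,
during and after the confinement. This vignette explains the models behind
each stage, the parameters that matter, and the choices we made where the
methodology was genuinely open.

## Input model

The universal input is an OTU count table: integer read counts per
(sample, OTU) pair, carried as a long tibble. Per-sample metadata give the
subject, the collection day relative to habitat entry (day 0; exit at day
520 by default) and the phase (`pre`, `confinement`, `post`). Taxonomy is
a seven-rank lineage per OTU; a rooted phylogeny with branch lengths is
needed only for UniFrac. Classic OTU-as-rows TSV and BIOM-JSON v1.0 are
read and written; HDF5 BIOM is deliberately out of scope so that the
package has no binary-format dependency.

## Trajectory normalization

Raw counts are converted to fractional abundances (per-sample sum one).
For each subject three further steps stabilize the trajectories:

1. **High-abundance selection.** Each OTU's median fractional abundance
   across the subject's time points is computed; OTUs are ranked by that
   median and the smallest prefix whose medians sum to 90% of the total is
   kept. The phrase "90% of the median time-point reads" admits another
   reading (the median *sample*); we implement the per-OTU-median reading,
   which matches the established dense-time-series normalization
   procedure, and expose the threshold as the `coverage` argument.
2. **Reference community.** Every sample is normalized against a
   sample-specific reference: for target sample *s*, each time point *t*
   receives weight $(1-j_{ts})^2$, where $j_{ts}$ is the Jensen-Shannon
   distance between the two samples' high-abundance profiles
   (renormalized over that subset, so weights live on the same support as
   the values being normalized). The reference value of each OTU is the
   weighted median of its abundances over time. The target's own time
   point participates with weight 1 — nothing in the formula excludes it,
   and dropping it would bias references at isolated time points.
3. **Scale factor.** The sample is rescaled by the median of
   reference/observed ratios over OTUs positive in both — a zero-robust
   median-of-ratios depth correction. The normalized matrix equals the
   observed abundances times that factor.

JSD uses base-2 logarithms throughout, so distances lie in $[0,1]$ and the
$(1-j)^2$ weights stay in $[0,1]$.

**Horizon bands.** For display and for screening volatile OTUs, each
normalized OTU series is median-centered and sliced into bands of width
one *unscaled* median absolute deviation (no 1.4826 consistency factor —
the bands are a visual convention, not a variance estimate), capped at
four bands per side, negative bands mirrored upward. A zero MAD sends any
off-median value to the outermost band.

## Steady states

Within a subject, samples are clustered by Ward linkage
(`stats::hclust`, method `ward.D2`) on the JSD matrix. Cutting the tree at
a height partitions the time series into *steady states*; states are
numbered by first appearance in time and maximal runs of consecutive
samples form episodes, from which persistence and recurrence statistics
derive.

**Choosing the cut height.** A fixed height is only meaningful relative to
one dataset's Ward scale, so `detect_states(height = "auto")` scans every
distinct clustering on the merge-height grid (requiring at least two
samples per state) and keeps the cut with the highest mean silhouette
width against the JSD matrix. Statistical validation is then run on the
chosen cut, not used to choose it. We separated selection from
certification deliberately: a Ward cut is by construction the most
separated partition of the very matrix being tested, so "pick the lowest
height whose groups pass a pairwise PERMANOVA" degenerates — data-driven
sub-splits of homogeneous noise pass a naive label-permutation test far
more often than the nominal level, and conversely two small states can
never reach small p-values (two groups of five samples admit only
`choose(10,5) = 252` label arrangements). The silhouette criterion
recovers planted regime structure reliably (see the acceptance tests) and
keeps the certification honest.

**Validation.** Certification of a cut follows two criteria: (i) every
within-state sample pair must show a significant Spearman rank correlation
of OTU profiles after Benjamini–Hochberg correction across all pairs
(q < 0.05; BH is our reading of "the q-value method" — Storey's estimator
adds a density estimate that small pair counts cannot support); and (ii)
states must differ by permutational MANOVA on the JSD matrix, overall and
pairwise. Pairwise tests switch to exhaustive enumeration of label
arrangements whenever feasible, making small-group p-values exact. The
PERMANOVA statistic is Anderson's pseudo-F computed directly from the
distance matrix; permutation p-values use the `(count + 1)/(n_perm + 1)`
convention. Pairwise p-values are not multiplicity-corrected by default
(a flag enables BH), matching common practice of reporting raw pairwise
PERMANOVA significance.

State profiles are per-OTU medians over member samples, renormalized to
sum to one — renormalization is documented because a median of
compositions is not itself a composition.

## Source attribution of state transitions

How much of a new steady state derives from the subject's own immediately
preceding state, and how much from elsewhere? Each transition treats the
new state's profile as a *sink* and offers as *sources* the subject's
preceding state plus every steady-state profile of every other subject,
plus an implicit *unknown* source.

Mixing proportions are estimated with a collapsed Gibbs sampler over
latent per-read source assignments. Known sources contribute a fixed
Dirichlet-smoothed emission term $(c_{kt} + \alpha_1)/(C_k + \alpha_1 T)$;
the unknown source's emission distribution is collapsed over the reads
currently assigned to it with smoothing $\alpha_2$; a prior count $\beta$
acts on the assignment proportions. Defaults are the published
source-tracking values ($\alpha_1 = 0.001$, $\alpha_2 = 0.1$,
$\beta = 10$), with 100 burn-in sweeps, 10 retained draws spaced 10 sweeps
apart, and 10 restarts; the inner loop is compiled (Rcpp) and draws from
R's RNG, so runs are reproducible under `set.seed`. Profiles are
compositions but the sampler needs reads, so sinks and sources are
rescaled to a pseudo-depth (default 10,000) by largest-remainder rounding.

The **exogenous score** of a transition is $e = 1 - \pi(\text{own
preceding state})$: the estimated fraction of the new state *not*
explained by the subject's own prior community. Within each subject the
scores are standardized with the population (n-denominator) standard
deviation; $z = 0$ therefore means "a change of this subject's average
magnitude", and transitions with $z$ above a threshold (default 1.5) are
flagged as major change events. With $k$ transitions the largest
attainable $|z|$ is $\sqrt{k-1}$, so flags are only meaningful for
subjects with at least four transitions. All other subjects' states are
offered as sources simultaneously, without temporal restriction — the
source description does not restrict them, and restricting to
contemporaneous states would make early transitions unattributable.

## Beta-diversity trend

Between-subject (beta) diversity over time uses UniFrac: unweighted
(presence/absence of tree leaves; the fraction of branch length unique to
one sample) and weighted (abundance-weighted branch differences,
normalized Lozupone variant by default, raw variant behind a flag).
Presence means fractional abundance above zero; we do not rarefy —
rarefaction discards reads and its depth choice would be data-dependent.
Samples from different subjects are matched by nearest collection day
within a ±3-day window (configurable), and all between-subject pairs at
each matched day form the distance series.

The temporal trend is fit by median (L1) regression — minimizing the sum
of absolute residuals — because distance distributions are bounded,
skewed, and contain pair-level outliers. For up to 200 points the exact
optimum is found by exhaustive search over lines through data-point pairs
(the L1 optimum interpolates at least two points); above that an
iteratively reweighted least-squares approximation is used. Significance
comes from a case-resampling bootstrap of the slope:
$p = 2\min(\hat F(0), 1 - \hat F(0^-))$ with a $+1/(n_\text{boot}+1)$
continuity correction. The slope is also reported rescaled by (day span /
distance range) and (day span / distance standard deviation); we define
these scalings explicitly rather than reverse-engineering any particular
published magnitude.

## Co-abundance groups

Within a subject, OTUs whose mean relative abundance across steady-state
profiles exceeds 0.1% are analysed for co-abundance: pairwise Kendall
τ-b across state profiles (exact enumeration p-values for up to 8
observations — tie-safe — and the tie-corrected normal approximation
above; 9 and 10 observations would mean 0.4–3.6 million arrangements per
OTU pair, beyond desk scale, so the cutoff is an argument), Ward
clustering on 1 − Spearman ρ, and a cut into 3 or 4 groups. The group
count is chosen by mean silhouette width with a small parsimony margin
(default 0.02): sub-splitting a tight group can raise the silhouette by a
sliver, and the margin prefers the coarser partition unless the finer one
is clearly better.

Certification again respects the data-driven grouping: the observed
partition's pseudo-F is compared against a null in which each OTU's
abundance vector is permuted across states independently (destroying
inter-OTU correlation) and the clustering is re-run in full, recording the
best pseudo-F achievable on decorrelated data. Under independent noise
this test keeps close to its nominal level, where a naive label
permutation would certify nearly every Ward partition. Network edges
connect OTU pairs with positive, significant τ (p < 0.05), weighted by τ;
per-state over-abundance is the ratio of state abundance to the
across-state median background with a 10⁻⁶ pseudocount guarding zeros.

Observations for all of this are steady-state *profiles*, not raw time
points: n is small (one observation per state), which is why exact
enumeration p-values and the small-n caveat are built in.

## The synthetic cohort generator

Because a real confinement cohort cannot ship with a package, every stage
is exercised against `generate_cohort()`, which plants known structure:

* 6 subjects, 27 samples each on a common day grid from −10 to 700
  (entry 0, exit 520), per-sample depth uniform in 7,759–91,366 reads,
  200 OTUs assigned to five phyla with subject-skewed frequencies —
  the shape and printed ranges of the motivating study design;
* per subject, 5–7 regimes (planted steady states), each a distinct
  Dirichlet baseline over the subject's OTU support (30% of OTUs
  cohort-shared, the rest subject-private), with samples drawn
  Dirichlet-multinomial around the active regime's baseline
  (concentration 500 by default — overdispersion typical of amplicon
  replicates; concentration is the single noise knob);
* one allochthonous injection event per subject (90% replacement by
  another subject's community at a day in 330–360, mirroring the reported
  timing of major change events), as a convex blend of compositions;
* a slow linear growth (default 2 × 10⁻⁴ per day, capped at 5%) of a
  cohort-wide rare-taxon blend after entry, so subjects' presence/absence
  profiles converge over confinement. No quantitative effect size for
  this convergence is published; the default is a free parameter chosen
  to be detectable but small, not a calibrated one;
* a random coalescent tree with exponential branch lengths over the OTUs
  (topology unconstrained by taxonomy — sufficient to exercise UniFrac).

What the generator does **not** emulate: within-regime autocorrelation,
strain-level dynamics, diet covariates, or taxonomically structured
phylogeny. Passing tests therefore demonstrate statistical correctness of
the machinery on overdispersed compositional count data with planted
regime structure — not biological fidelity, and not the original study's
printed numbers, which depend on its deposited sequencing data.

## Numerical conventions and problem sizes

* `0 log 0 = 0` in all KL terms; compositions are renormalized on entry.
* Weighted median: the smallest value whose cumulative weight reaches
  half the total (the lower weighted median).
* Permutation p-values: `(count + 1)/(n_perm + 1)`; exact enumerations
  report the unadjusted fraction including the observed arrangement.
* Ties in silhouette-based k selection resolve to the smaller k.
* Stage-level seeds derive from the global seed by a stable hash of the
  stage name, so adding a stage never shifts another stage's stream.
* Default problem sizes in tests and the acceptance script (150–200 OTUs,
  15–27 samples per subject, 199–1,999 permutations, 10–20 replicate
  seeds) were chosen as the smallest sizes at which the planted effects
  are comfortably identifiable; all scale linearly if increased.

## Known limitations

* The auto height criterion assumes steady states are at least two
  samples long; a genuine one-sample excursion is absorbed into a
  neighbouring state.
* Kendall p-values with more than 8 observations per subject use the
  normal approximation, which is rough under heavy ties at small n.
* The IRLS fallback for L1 regression is an approximation; it is only
  used beyond 200 points, where the pairwise search would be quadratic
  in memory.
* The Gibbs sampler treats source profiles as fixed (fully collapsed
  known sources); uncertainty in the source profiles themselves is not
  propagated.
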