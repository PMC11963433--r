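---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rejuvenome` re-implements, as tested and seeded code, the statistical
machinery of a life-long fecal microbiota rejuvenation experiment in mice:
two arms (yMB, recipients of young-donor microbiota; iMB, recipients of
age-matched donor microbiota) followed from week 8 to week 120, profiled by
metagenomics (KEGG ortholog abundances), 16S amplicon sequencing (ASV
counts), single-cell RNA sequencing of the intestinal mucosa, and host
phenotyping. Every analysis runs end to end on synthetic data with known
ground truth, so the package can measure its own error rates instead of
asserting them. This vignette documents the models, the tunable parameters
and why their defaults are what they are, and the design decisions taken
where the underlying procedures left room.

## The aging-inversion screen

For each microbial metabolic feature (KEGG ortholog), raw abundances are
prevalence-filtered (non-zero in at least 10% of samples, inclusive
boundary), total-sum scaled per sample, and transformed by
`log10(x + 0.01) + 2`. The offset-and-shift form is chosen so that a
relative abundance of exactly zero maps to exactly zero while non-zero
values are perturbed only minimally; the package treats this identity as a
hard contract (`transform_ko(0)` is bit-exact `0`). Feature families without
structural zeros (ecological relationship abundances) use a plain `log10`.
Scale tags on the table (`raw -> relative -> transformed`) make an
out-of-order pipeline an error rather than a silent mistake. Filtering uses
the raw zero pattern; since total-sum scaling preserves zeros, filtering
before or after normalization is equivalent, and the package filters first.

Each transformed feature is then modeled with

```
y ~ age * treatment + (1 | mouse)
```

fitted by REML (`lme4`), with iMB as the treatment reference and age in
weeks, uncentered. Under that coding the fixed-effect coefficient of age is
directly the iMB age slope and the yMB slope is the sum of the age and
interaction coefficients, which is what the downstream direction
classification consumes. The age-by-treatment interaction is tested with a
Wald t statistic using containment degrees of freedom, `n_obs - n_mice - 2`:
for the balanced designs the generator produces this equals the Satterthwaite
df exactly, and it avoids the mild small-sample anticonservativeness of a
normal reference. Interaction p values are Benjamini-Hochberg adjusted
across all converged features; fits that fail outright are excluded from the
adjustment (reducing m) and labelled `fit_failed`. A fit whose random-effect
variance collapses to zero is *not* treated as failed: its fixed effects are
still the least-squares estimates (the two coincide in balanced designs),
which is exactly the degenerate limit the noise-free recovery tests operate
in. If `lme4` errors out entirely, the feature falls back to ordinary least
squares with the same fixed-effect structure.

Features at FDR <= 0.05 are classified from their two age slopes: strictly
opposite signs are `inverted` (the age trend reverses under the young
microbiome), both positive `concordant_up`, both negative
`concordant_down`. A slope of exactly zero is a measure-zero event under
any continuous model, so it is surfaced as `indeterminate` rather than
being silently assigned to a bin.

Pathway membership of the significant features is tested with a one-sided
upper-tail hypergeometric test per pathway (tested size between 3 and 500
members inside the universe), BH-adjusted across the tested pathways;
reported rows need raw p <= 0.05 and an overlap of at least 3 features.
The universe is all features that carry at least one pathway annotation —
the conventional default of over-representation tools, recorded here as an
explicit assumption. The BH family is the set of *tested* pathways, not all
annotated pathways. Pathway-level effect sizes are the arithmetic mean over
member features of per-feature log2 ratios of mean relative abundance at
120 vs 72 weeks within each arm; a group mean of exactly zero receives a
pseudocount of half the smallest non-zero relative abundance in the table
and is flagged in the output.

## Ecological relationships by flux balance analysis

Pairwise microbe-microbe relationships are inferred from growth effects in
co-culture. The package ships a small, complete FBA engine: a model is a
stoichiometric matrix with finite flux bounds and a biomass reaction, and
growth is the biomass optimum of the linear program `max c'v` subject to
`S v = 0`, `lb <= v <= ub`. The LP core is a dense two-phase simplex with
Bland's rule, which cannot cycle; at the toy scales used here (tens of
reactions) a dense tableau is the simplest correct choice, and every optimum
is property-tested against steady state and bounds to 1e-8. Infeasibility
is a *result* (growth 0, flagged), not an error — an organism that cannot
grow on a medium is biology; an unbounded objective is a model defect and an
error.

Co-culture models share one extracellular compartment: member reactions and
cytosolic metabolites are namespaced, member-level exchange reactions are
replaced by a single community exchange per extracellular metabolite, and
medium bounds are applied once, so shared resources are genuinely contested.
Because the joint optimum of a community LP is usually degenerate (any split
of a shared substrate maximizes the sum), the allocation between members
must be pinned down by a protocol. The default maximizes joint biomass
`g1 + g2`, then runs flux variability analysis on each member's biomass at
that optimum and reports the midpoint of the feasible range — deterministic
and symmetric under member exchange. Two alternatives are selectable
(`lexicographic` and a 50:50 `equal_split` of uptake bounds) because the
allocation rule is a genuine modelling choice, not a derived fact.

The effect of co-culture on member *i* is `g_pair_i - g_alone_i`; its sign
is zero inside a neutral band `max(tol_abs, tol_rel * g_alone)` with
defaults `tol_rel = 1e-6`, `tol_abs = 1e-9`, which separate LP round-off
from real effects at the scales of the toy models. The unordered sign pair
maps onto the six classical relationship types: (+,+) mutualism, (+,0)
commensalism, (+,-) exploitation, (0,0) neutralism, (0,-) amensalism,
(-,-) competition — and sign-pattern enumeration closes over exactly those
six. "Antagonistic" interactions are defined as any pattern with a negative
effect on a member ({competition, amensalism, exploitation}); the set is a
configurable argument since the term has no unique formal definition.
Community-level profiles tally the relationship types over all pairs of
members detected above a relative-abundance threshold (default: any
non-zero abundance); an abundance-weighted tally (weight = product of the
two members' relative abundances) is available behind a flag because it is
not stated whether published community frequencies were weighted.

The six generator fixtures are hand-constructed so that each relationship
arises mechanistically, not by assertion: a shared limiting substrate for
competition, disjoint substrates for neutralism, one-way byproduct feeding
for commensalism, obligate two-way cross-feeding for mutualism, a forced
substrate drain for amensalism, and an obligate byproduct consumer that
outcompetes its producer for exploitation. The full chain (mono-culture
FBA, pair construction, co-growth, sign classification) must return the
intended class for every fixture at every seed; the seed jitters the shared
uptake bound over 8-12 mmol/gDW/h.

## Community trajectories

ASV counts are rarefied — seeded subsampling without replacement — to the
minimum shared read count before any diversity computation, mirroring
standard practice for unequal sequencing depth. Bray-Curtis dissimilarity
`sum|u - v| / sum(u + v)` is computed on rarefied relative abundances. The
trajectory statistic is each sample's distance to the week-8 baseline: by
default to its own mouse's baseline sample, falling back to the centroid
(mean relative abundance) of its arm's baseline samples when that mouse has
no baseline; a pure-centroid mode is also exposed, since the reference
choice is not fixed by convention. Arms are compared per timepoint with a
Mann-Whitney test. Ordination is classical (unconstrained) PCoA via double
centering and eigendecomposition; negative eigenvalues — expected for
Bray-Curtis — are reported and their axes dropped. Constrained ordination
(CAP) is deliberately out of scope: it is a published composite method that
this package would only be calling, not implementing.

## Single-cell mucosa analysis

Cells are filtered on four conjunctive criteria: total counts in
[200, 5000] (both bounds inclusive — the removal rules are "less than 200"
and "more than 5000"), mitochondrial fraction at most 25%, housekeeping
fraction at least 10%. "Reads mapping to the genome" is interpreted as the
cell's total counts. Mitochondrial genes are recognized by the `mt-`
prefix and housekeeping genes by a packaged default list; both are
configurable because no canonical list is mandated. Normalization is
library-size scaling to 10,000 followed by `log(1 + x)`, the long-standing
single-cell convention.

Module scores follow the additive control scheme common in the field: the
per-cell mean of the signature genes' normalized expression minus the mean
of a seeded control set drawn from expression-matched bins (24 bins over
average expression, 100 control genes per signature gene). The exact
scoring formula used upstream of the original figures is not printed
anywhere, so this implementation is declared an emulation of the standard
scheme, with the self-control identity (control set = signature implies a
score of exactly 0) as its anchor test. Scores are compared per cell type
with Mann-Whitney tests, BH-adjusted across cell types.

Differential expression per cell type uses a Wilcoxon rank-sum test on the
normalized expression with a minimum absolute log-fold difference of 0.1,
where the fold is the difference of group means of natural-log-normalized
expression — natural log, following the Seurat-era convention; this base
choice is flagged prominently because "log-fold 0.1" is ambiguous without
it. Significance is Bonferroni-corrected with the full gene complement of
the dataset as the family, and reported genes need adjusted p < 0.05.
Cell-proportion differences are tested per cell type on per-mouse
composition vectors with Mann-Whitney tests. Cell-type labels are consumed
as given (synthetic or user-provided); annotation itself is out of scope.

## Host phenotype statistics

Windowed trapezoidal AUC summarizes weight (weeks 80-120) and glucose
tolerance (0-120 min) curves; when no observation falls exactly on a window
edge the curve is linearly interpolated there, because the window of
interest is fixed but the sampling grid is not. Group comparisons use a
two-sided Mann-Whitney test: exact by full enumeration when both groups
have at most 8 observations and no ties, otherwise the normal approximation
with tie and continuity corrections (the exact/asymptotic switch is also
settable explicitly; the cutoff of 8 keeps enumeration instant). Survival
is compared with the standard Mantel-Cox log-rank statistic (1 df). All
reported p values are two-sided.

## The synthetic-data generators

The generators are first-class, tested code; their defaults define the
study conditions the acceptance checks run under.

* **KO tables** are drawn directly on the transformed scale under exactly
  the screen's model: per-feature intercept, per-treatment age slope,
  per-mouse random intercept, Gaussian residual. Defaults: 10 mice per arm,
  timepoints 8/40/72/120 weeks, `slope_magnitude` 0.005 transformed
  units/week, `mouse_sd` and `noise_sd` 0.1. Inverted features get slopes
  of ±0.005 with alternating orientation; concordant features get same-sign
  slopes of 1.5x and 0.5x the magnitude (a real interaction without a sign
  flip); null features share one common slope drawn N(0, 0.0025), so the
  null hypothesis holds for the interaction in the presence of a genuine
  age main effect. Gaussian noise on the transformed scale — rather than a
  count model — is deliberate: it makes the generator match the screen's
  assumptions exactly, so parameter recovery is exact in the noise-free
  limit and calibration failures indict the screen, not the generator. The
  random intercept is drawn independently per mouse and feature, constant
  across timepoints, matching the per-feature model the screen fits.
* **ASV tables** are Dirichlet-multinomial: per mouse a baseline
  composition and a drift target around a shared log-normal community
  profile (concentration 50), expected composition mixed toward the target
  at `drift_per_week` (defaults 0.004/week for yMB, 0.008 for iMB — the
  faster drift in the isochronic arm is the planted direction), counts
  drawn at Dirichlet-multinomial concentration 200 and a uniform depth of
  8,000-12,000 reads. The double-Dirichlet structure produces the
  overdispersion that rarefaction has to absorb.
* **Cell matrices** are negative binomial with log-normal gene means, a
  fixed per-gene dispersion (size uniform in [1, 4]) and log-normal
  per-cell library factors — the simplest model under which the rank-based
  DE test is calibrated. Housekeeping genes get high means and `mt-` genes
  moderate means so the QC fractions are realistic. Signature shifts and
  planted DE fold changes are multiplicative on the mean (natural-log
  scale), applied in yMB cells of the targeted cell types.
* **Phenotypes**: saturating weight curves sampled every 8 weeks with
  mouse-level intercepts; a rise-and-clear glucose curve at the standard
  ipGTT minutes; exponential survival censored administratively at week
  120, with the arm hazard ratio as the planted effect.

One global seed fans out to per-component child seeds via a documented
affine splitting rule (`child_seed`), so adding draws to one generator
never perturbs the others. No effect-size scale for the real data is
published, so generator defaults were chosen once for reasonable test
power at desk scale and are not tuned afterwards.

What the generators deliberately do *not* emulate: read-level sequencing
artifacts, taxonomy, realistic mouse gut composition, cell-type marker
structure, doublets or ambient RNA, or count-scale KO abundances. Passing
tests therefore demonstrate that the statistical machinery is correct and
calibrated under its own assumptions — not that those assumptions hold in
any particular real dataset.

## Problem sizes and numerical choices

The calibration studies run at 250 features (200 null, 50 with a true
interaction), 10 mice per arm and 4 timepoints over 50 replicates; recovery
studies use 20 replicate seeds; the DE recovery fixture is 2,000 genes with
a single planted gene. These sizes were chosen so each property is measured
with useful Monte-Carlo precision while the whole suite stays interactive.
LP tolerances are 1e-9 in the simplex and 1e-8 in the steady-state
assertions; PCoA eigenvalues below 1e-10 are treated as zero; BH and
hypergeometric computations are exact. Mean false-discovery proportion is
compared to the nominal level with two Monte-Carlo standard errors of
slack, since 50 replicates estimate it with finite precision.

## Known limitations

* The mixed-model screen tests only the interaction; a main-effect filter
  on age, if the original analysis used one, is not applied (interaction
  significance alone is implemented).
* The Wald-t interaction test with containment df is exact for balanced
  designs; for severely unbalanced data a Satterthwaite or Kenward-Roger
  approximation would be preferable.
* The co-growth allocation protocol and neutrality thresholds are
  configuration, not claims of equivalence to any published tool's internal
  rule.
* Module-score mechanics (binning, control counts) emulate the common
  scheme; scores are comparable within this package, not across tools.
* Bray-Curtis PCoA drops negative-eigenvalue axes rather than applying a
  correction (Lingoes/Cailliez), which is adequate for visualization and
  the reconstruction tests but not for exact distance preservation of
  non-Euclidean inputs.
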