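---
title: "Methods: from ecosystem productivity to the timing of the Neanderthal replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ecosystem productivity to the timing of the Neanderthal replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

During Marine Isotope Stage 3 (MIS3, roughly 60--30 ka BP), Neanderthal-affiliated
industries (NAI: Mousterian, Micoquian, Châtelperronian) disappeared from Europe
while *H. sapiens*-affiliated industries (SAI: Aurignacian, Initial Upper
Paleolithic, Neronian, Uluzzian) spread in, with regionally very different timing.
`paleocc` implements an inference chain that asks whether the regional timing of
that replacement — and the temporal overlap between the two groups — is
associated with the ecosystem's capacity to support herbivores. The chain is:

1. filter and calibrate chronometric dates (two filtering criteria),
2. estimate per-region NAI end and SAI start by a hierarchical Bayesian phase
   model (BAM) and by optimal linear estimation (OLE),
3. delimit biogeographic regions from NPP-trajectory dissimilarity, climate
   class and herbivore guild composition,
4. convert net primary productivity (NPP) plus guild composition into herbivore
   carrying capacity (CC) by size class,
5. compute overlap durations and coexistence contrasts, and
6. test ecology--chronology associations with Moran-eigenvector spatially
   filtered (ESF) regression, propagating 95%-CI uncertainty by resampling.

Because the compiled archaeological dataset behind the published regional
summaries is not redistributable, the package pairs the analysis chain with a
fully synthetic world generator whose ground truth encodes the tested
hypothesis, so every stage can be exercised against known answers. The printed
regional summary tables themselves (16 regions: NPP statistics, CC by size
class, and the NAI/SAI chronology under both filtering criteria) ship as
plain-text fixtures for the desk-scale reproductions.

# Chronology

**Units.** Ages are handled internally in ka cal BP (BP = 1950), larger =
older. Input tables declare their units and are converted on read.

**Filtering.** Both criteria always drop conventional (non-AMS) radiocarbon
measurements, QC-flagged records (potential contamination, low collagen yield,
burnt bone) and dates whose coefficient of variation (error/age) is 0.05 or
larger. Criteria 2 (FC2) additionally keeps only dates on material brought or
modified by humans. Techno-complexes without diagnostic human fossils
(Szeletian, Bohunician, LRJ) are always excluded; the contested
Châtelperronian and Uluzzian attributions are sensitivity toggles.

**Calibration.** Radiocarbon dates are calibrated on a 0.005 ka (5 yr) calendar
grid, truncated at ±5σ: the posterior is proportional to a normal likelihood
with variance equal to lab error² + curve error² (+ reservoir-offset error²),
normalised to unit mass. The grid step balances accuracy against the cost of
calibrating hundreds of dates; with monotone curves the posterior mode is
grid-exact on round trips. OSL/TL/U-Th dates bypass the curve as normal
densities with their 1σ error. Marine dates require a marine-flagged curve and
use a reservoir offset ΔR = 0 (the offset is unknown at these ages and is
proportionally small). Replicate measurements on one sample are combined by
inverse-variance weighting with a χ² consistency statistic before modelling.

**Bayesian phase model.** Each event is one chronometric date. The sampler
places a uniform prior on the study window for each event's true age; the
likelihood is a Gaussian summary of the event's calibrated density inflated by
an event-level extra variance under a shrinkage prior (exponential, mean equal
to the squared calibrated sd). This is a deliberate simplification: it keeps
the phase boundaries free of the hyperparameters that, in other phase priors,
pull boundaries toward the most precise date, and therefore yields wider,
more conservative credibility intervals. The Gaussian summary is adequate for
monotone (toy) curves; strongly multimodal calibrated densities would be
approximated. Phase start/end are the per-iteration max/min of member ages;
three chains with distinct seeds are pooled after burn-in, convergence is
checked by a split-chain diagnostic with threshold 1.05. The posterior mode is
a kernel-smoothed density argmax; HPD intervals are shortest-interval searches
on the sorted samples, with the 68% interval clipped into the 95% envelope
(sample-level searches can violate the nesting that holds for density-level
HPDs by a fraction of a grid step).

**Optimal linear estimation.** The Solow--Roberts estimator is applied to the
k most extreme sightings (k between 5 and 10; regions with fewer than 5 dates
are refused): the joint Weibull shape is estimated from log-spacing ratios and
the optimal weights from the inverted extreme-order covariance matrix. The
estimated endpoint is constrained not to precede the most extreme sighting.
First appearances are handled by reflecting the time axis. Chronometric
uncertainty is propagated by redrawing every sighting from a normal
distribution with its 1σ error (10,000 times by default; routine runs scale
this down): the point estimate is the median of the resample distribution and
the 95% CI its 2.5/97.5 percentiles. Under the simulation conditions used in
the tests (10 sightings uniform over 7 ka, 0.5 ka errors — a typical
calibrated 1σ at these ages), this CI covers a known endpoint in roughly
80--95% of records.

**KDE overlap surfaces.** Per 1-ka bin, each date contributes its calibrated
mass in the bin, spread over a 0.5° raster by a Gaussian kernel with σ =
150 km of great-circle distance (haversine, radius 6371 km); the overlap stack
is the elementwise product of the NAI and SAI stacks.

# Biogeography

NPP trajectories are compared with the dCORT dissimilarity: the Euclidean
distance between series, weighted by `2 / (1 + exp(k * CORT))` where CORT is
the correlation of first differences (k = 2 by default; k = 0 recovers plain
Euclidean distance). The base distance is raw Euclidean and configurable.
Clustering is agglomerative with average linkage (the linkage is not pinned
by the published analysis; average linkage is the common default for
ecological dissimilarities), with deterministic relabelling by smallest
member id and a largest-relative-gap rule for the default cut. Climate is
classified with a Peel-style Köppen-Geiger threshold table restricted to the
C/D/E families (hottest month ≥ 22 °C gives "a"; ≥ 4 months at ≥ 10 °C gives
"b"; a hottest month of 0--10 °C gives tundra), shipped machine-readably in
`extdata/koppen_rules.tsv`. Guild composition is compared with the Jaccard
dissimilarity. Regions are the refinement of the NPP clusters split wherever
climate class or fauna cluster differ — the partition never merges NPP
clusters — and are numbered east to west by mean longitude. Site-level series
(rather than regional means) are clustered, and no polygon/GIS machinery is
used: regions are site memberships.

# Herbivore carrying capacity

The exact published parameterisation of the CC model is not available, so the
package implements the documented structure with explicit, configurable
defaults — these are package defaults, not published calibrated values:

* individual density follows a Damuth-style allometry `a * M^b`, with
  a = 91.2 ind/km² and b = −0.73;
* guild members share the total supportable biomass in proportion to their
  expected biomass density `a * M^(b+1)`;
* total herbivore biomass is `f * 1e6 * npp_ref * (NPP/npp_ref)^beta`
  kg/km²/yr with β = 1 (linear in NPP) and the transfer fraction f = 0.0027
  chosen so that a reference NPP of 0.3 kg/m²/yr supports ≈ 810 kg/km²/yr,
  the order implied by the packaged regional table's size-class sums
  (the 1e6 converts kg/m² to kg/km²);
* size classes split at 20 and 300 kg, both bounds inclusive to medium,
  matching the published size-class definition; species under 1 kg are
  rejected at ingest.

95% CIs are Monte-Carlo: log-normal draws for a and f, normal for b, each
draw time-averaged before summarising (time-average of draws, since the
alternative ordering is not documented). Note that a cancels out of the guild
shares and only matters for density validation. Because the CIs are
percentile-based, their widths *stabilise* rather than shrink as draws
increase; tests assert convergence at 10× draws. Validation against modern
densities correlates predictions and observations on a log10 scale (the
allometry spans orders of magnitude), per park (≥ 3 matched species) and
pooled. Guild completeness uses incidence-based rarefaction with Chao2-style
extrapolation and a 500-replicate bootstrap CI.

# Coexistence summaries

The minimal overlap is the youngest SAI-start 95% bound minus the oldest
NAI-end 95% bound (the construction that reproduces the one printed overlap,
4.8 ka in the lower Danube Basin); a 68% variant is available. The central
overlap is the difference of posterior modes. Coexistence is defined as
minimal overlap > 0 — but note that this rule does not rederive the published
four-region no-coexistence partition from the printed chronology tables alone
(other regions' modes also fail to overlap), so that partition
{R_2, R_3, R_13, R_16} is also shipped as data and accepted as an explicit
input by the group comparisons. Group contrasts are unweighted means with
percent difference `100 * (1 − mean_no / mean_co)`; this reproduces the
printed 27/49/41/29% contrasts from the packaged table within rounding. The
printed "39% higher CV" contrast is not reproducible from the packaged table
under any aggregation we tested and is deliberately not targeted.

# Spatially filtered correlation tests

Regions are not independent observations: neighbours share ecology. The
package builds inverse great-circle-distance weights (the weighting scheme is
not pinned by the published analysis; a distance-band alternative is
provided), extracts eigenvectors of the doubly-centered weight matrix
`M W M`, retains candidates with eigenvalue above 0.25 of the maximum, and
forward-selects the candidate that most reduces the absolute residual
Moran's I until the residual autocorrelation is no longer significant
(permutation test, threshold 0.10) or no candidate improves it. The
coefficient of interest keeps its ordinary two-sided OLS p-value.
Estimate uncertainty is propagated by redrawing every dependent and
independent value from a two-piece normal implied by its 95% CI
(sd = half-width/1.96 per side) and refitting, 10,000 times by default;
results are reported as coefficient and p-value distributions and the
fraction of resamples with p ≤ 0.05. No multiple-testing correction is
applied across variable pairs, matching the distribution-style presentation
of the original analysis. Regions with no SAI representation are dropped
from overlap regressions.

In the pipeline's overlap regressions, the overlap CI half-width combines the
SAI and NAI interval widths in quadrature (independent phase posteriors).

**Calibration of the test.** The type-I simulation draws the response as the
generator's spatial noise (exponential covariance, 500 km range, 1 ka sd)
plus region-independent estimation noise of the same scale — the operating
condition of the package's regressions, where chronology estimation noise is
comparable to the spatial noise (OLE CI half-widths are ≈ 1 ka under the
default error models). Under that null the measured type-I error is ≈ 0.06 at
nominal 0.05 over 2000 replicates. With a purely spatial response and no
observation noise the post-selection inference is slightly more liberal
(≈ 0.07--0.08): forward selection on data-dependent criteria is known to be
mildly anti-conservative, which is a limitation of the ESF approach itself.

# The synthetic world

`world_config()` defaults define the emulated study conditions: 16 regions ×
20 sites on a European-like lon/lat extent, window 55--30 ka BP,
stadial/interstadial square wave with ≈ 1.5 ka phases (Dansgaard-Oeschger
pacing) and jittered change points, base NPP 0.28 kg/m²/yr with per-region
levels spanning ≈ 0.17--0.36 (the packaged table's range), amplitude 0.05,
AR(1) noise 0.015. Lab errors are uniform on 200--600 radiocarbon yr; 85% of
dates are anthropic, with small fractions of conventional and QC-flagged
records so both filtering criteria have work to do. The true overlap of a
region is `1.0 + overlap_effect × (CC_med − mean) + spatial noise` with
`overlap_effect = 0.02` ka per kg/km²/yr and spatially autocorrelated noise
(exponential covariance over great-circle distance, 500 km range, 1 ka sd) —
chosen so that true overlaps span ≈ −3 to +5 ka, the order of the published
regional spread. The generator stores true ages in a hidden column used only
by recovery tests.

What the generator does *not* emulate: multimodal calibration plateaus, real
geography and ice-sheet masking, inter-laboratory error structure (a single
lab-error term is used; the compiled-data error structure is unpublished),
taphonomic loss gradients, and any climate-model dynamics (the
square-wave-plus-noise signal only reproduces the mean/CV structure the
downstream stages consume). Passing recovery tests therefore demonstrates the
statistical machinery is calibrated under these idealised conditions, not
that the published compiled dataset would yield the same numbers.

# Problem sizes and numerical choices

Routine test runs use scaled-down resample counts (a few hundred CI draws,
30-region worlds, 50 phase fits with 3 × 6000 iterations thinned by 4), which
keep every simulation's Monte-Carlo error well inside the asserted bands.
Degenerate inputs are handled explicitly: identical sightings return their
common value; empty species pools return empty incidence tables; all-equal
metrics classify as "M"; zero-width CIs collapse the resampling to the single
fit; two empty assemblages have Jaccard dissimilarity 0 by convention.
Deterministic tie-breaks: cluster labels by smallest member id, east-west
region numbering by mean longitude with first-occurrence ties.

# Known limitations

* The CC parameter defaults are structural stand-ins; absolute CC levels are
  only comparable across regions, not interpretable as abundances.
* The coexistence flag from minimal overlap does not reproduce the published
  partition; the partition is accepted as input where the published contrasts
  are reproduced.
* The BAM is a simplified event-level phase model, not a reimplementation of
  any specific chronological modelling software.
* ESF post-selection inference is mildly anti-conservative under purely
  spatial nulls (see above).
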