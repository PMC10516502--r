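# paleocc

Did ecosystem productivity shape where and when Neanderthals disappeared,
where *H. sapiens* spread first, and how long the two overlapped? `paleocc`
is an R package for palaeoecologists and archaeological scientists that
implements the full inference chain behind that question for Europe during
Marine Isotope Stage 3 (~55–30 ka BP):

* **Chronology** — chronometric date filtering under two criteria (all
  reliable dates vs human-modified material only), radiocarbon calibration
  against IntCal-dialect curves, same-sample combination, a hierarchical
  Bayesian phase model (per-event true ages θᵢ with uniform window priors and
  shrinkage-prior extra variance; phase start/end = per-iteration max/min θᵢ),
  Solow–Roberts optimal linear estimation (OLE) of first/last appearances
  with 10,000-draw uncertainty resampling, and spatiotemporal KDE overlap
  rasters (Gaussian kernel, σ = 150 km, 1-ka bins).
* **Biogeography** — dCORT time-series dissimilarity
  `φ_k(CORT) · d_Euclid` with `φ_k(u) = 2/(1+e^{ku})`, average-linkage
  clustering, Köppen–Geiger climate classes, Jaccard guild dissimilarity,
  and region delimitation as the climate/fauna refinement of the NPP
  clusters, numbered east to west.
* **Carrying capacity** — an allometric, NPP-driven herbivore model:
  individual density `a·M^b` (Damuth-style defaults a = 91.2, b = −0.73),
  biomass shares ∝ `a·M^{b+1}`, total biomass `f·10⁶·NPP` kg/km²/yr,
  size classes small (<20 kg) / medium (20–300 kg) / large (>300 kg),
  Monte-Carlo CIs, validation against modern density tables, and
  incidence-based rarefaction with bootstrap CIs.
* **Coexistence and inference** — minimal/central NAI–SAI overlap per region,
  group percent differences, and Moran-eigenvector spatially filtered (ESF)
  regression with 95%-CI resampling of both variables.
* **Synthetic worlds** — a generator with known ground truth (true regional
  overlap linear in true medium-size carrying capacity) so every stage has
  recovery tests; the published 16-region summary tables ship as plain-text
  fixtures.

## Worked example

```r
library(paleocc)

cfg <- pipeline_config(
  world_config(n_regions = 16, sites_per_region = 20, seed = 42),
  criteria = c("fc1", "fc2"),
  esf_n_resamples = 1000,
  ole = ole_config(n_resamples = 1000))
run <- run_pipeline(cfg)
cat(make_report(run), sep = "\n")
```

```
paleocc pipeline run (config 0051bd3e, seed 42)

== criteria fc1 ==
8/16 regions with temporal overlap > 0
medium-size CC 25% lower in no-coexistence regions
CC-overlap test: median coefficient 0.0154, median p 0.0189, 73% of resamples significant

== criteria fc2 ==
8/16 regions with temporal overlap > 0
medium-size CC 25% lower in no-coexistence regions
CC-overlap test: median coefficient 0.0153, median p 0.0218, 69% of resamples significant
```

The generated world linked true overlap to medium-size carrying capacity with
slope 0.02 ka per kg/km²/yr; the recovered median coefficient (0.0154, p ≈
0.02 after spatial filtering and CI resampling) and the recovered-vs-true
overlap correlation (r = 0.98 across the 16 regions) show the chain
recovering its ground truth. On the packaged published tables, the desk-scale
checks print:

```r
ov <- temporal_overlap(read_chronology_fixture("fc1")$R_1)
ov$minimal_ka
#> [1] 4.81     # minimal NAI-SAI overlap in the lower Danube Basin, ka
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → chronology → regions & CC → coexistence & ESF →
reference-table summaries), writing their tables under `results/`.

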