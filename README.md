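# reeftrack

Positional acoustic telemetry analysis for site-attached reef fish, as
one tested pipeline:

1. **Simulate** (or ingest) — a correlated-random-walk fish with four
   labeled movement modes (scanning, dwelling, fast ranging, slow
   ranging), a triangular receiver lattice, range-dependent detection,
   receiver clock errors, and sync beacons.
2. **Synchronize** — per-window network least squares on pairwise beacon
   arrival differences removes receiver clock offsets and drift.
3. **Localize** — difference-of-time-of-arrival (DToA) positioning by
   exhaustive coarse-to-fine minimization of the summed pairwise
   hyperbolic mismatch at the tag's depth (compiled kernel).
4. **Prepare** — per-day quality control (≥30 fixes in every daytime
   hour, ≥2 consecutive accepted days) and linear interpolation onto a
   1-minute sunrise-to-sunset grid.
5. **Home range** — alpha-shape boundary with a tunable shrink factor,
   kernel utilization distribution, time-conserving occupancy maps, and
   range-stability comparisons (intersection over union).
6. **Segment features** — overlapping 30-minute path segments, each
   described by 13 geometric and temporal features.
7. **Classify** — correlation-scale PCA, Ward agglomeration, and a
   merger-score tree cut with a threshold-sensitivity report;
   auto-naming of classes from their kinematics, reviewer-controlled
   merges, and per-day class occupancy with stability standard errors.

Every stage is exercised against independent oracles (brute-force grid
search, direct Markov simulation, naive Lance–Williams agglomeration,
covariance eigendecomposition, closed-form geometry) in the `testthat`
suite.

## Worked example

Simulate one fish for four days, run the whole chain, and look at the
results (the printed output below is from a real run):

```r
library(reeftrack)
cfg <- pipeline_config(n_fish = 1, n_days = 4, seed = 5)
res <- run_pipeline(cfg)
```

```
clock model: 17 windows, reference R16
F1: 131386 detections
F1: 25279 fixes from 33850 transmission groups
F1: 4 days pass QC
F1: 188 segments -> 3 classes
pipeline finished in 0.7 min
```

```r
fish <- res$fish$F1
fish$home_range
```

```
Home range (alpha): area 29213.1 m^2 from 2884 points
```

```r
fish$pca
```

```
PCA of 13 features; 4 components explain 68.6% of the variance
  per-component: 29.0%, 20.5%, 10.6%, 8.5% 
```

```r
fish$clusters
```

```
Agglomerative clustering: 3 classes at 1.5% merger-score cut
  sensitivity: 1% -> 3, 1.5% -> 3, 2% -> 1, 3% -> 1 
  classes:

    dwelling fast ranging slow ranging 
          66           36           86 
```

```r
fish$occupancy_by_class
```

```
Class occupancy over 4 days
  mean daily fractions:
    dwelling fast ranging slow ranging 
       0.349        0.193        0.458
```

Writing `run_pipeline(cfg, out_dir = "out")` additionally produces
per-stage CSV/GeoJSON artifacts plus a `manifest.json` recording the
package version, seed, and parameters; rerunning the same configuration
reproduces the outputs byte for byte.

A note on honesty: under the default simulator settings the
unsupervised cut does **not** recover the four generator modes as four
classes — segments mix modes, the skewed speed scale is compressed by
standard-deviation scaling, and localization noise swamps the slowest
modes, so the merge tree is gradual and the cut (correctly) reports
little structure. The methods vignette
(`vignettes/acoustic-telemetry-pipeline.Rmd`) documents the mechanism
and why real, place-bound fish behavior differs.

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "reeftrack",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

`scripts/acceptance.R` runs the installed package end to end on
simulated data and writes the pipeline's main computed quantities
(class counts, mode-recovery adjusted Rand index, localization and
clock-recovery errors, PCA variance fractions, home-range areas and
overlaps, occupancy conservation) as a flat JSON object.

## Package layout

| Path | Contents |
| --- | --- |
| `R/simulate.R` | movement modes, trajectory/detection/beacon simulators, receiver lattice |
| `R/localize.R` | clock model, detection correction, transmission grouping, DToA solver |
| `R/prep.R` | solar day windows, QC, 1-minute interpolation |
| `R/homerange.R` | alpha shape, KDE, occupancy, IoU, range stability, sleeping site |
| `R/features.R` | segmentation, 13 segment features, scaling |
| `R/cluster.R` | PCA, Ward tree, merger-score cut, labeling, class occupancy |
| `R/io.R`, `R/pipeline.R` | CSV/GeoJSON/YAML interchange, config, `run_pipeline()` |
| `src/` | compiled DToA error-map kernel (Rcpp) |
| `tests/testthat/` | per-module suites + `test-acceptance.R` |
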