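# phenosync

Phenological synchrony between satellite-derived vegetation green-up and
the breeding dates of woodland birds.

Great tits and blue tits raise their chicks on a brief spring peak of
caterpillars whose timing tracks tree leaf-out. Because leaf-out varies
across a woodland at scales of a few hundred metres, a single site-wide
phenology number hides most of what matters to an individual bird.
`phenosync` turns multispectral satellite time series into per-pixel
(240 m) spring green-up dates, maps them onto individual nestboxes, and
quantifies how tightly egg-laying follows local vegetation phenology —
across years, across individuals, and across space — including which
habitats show the tightest coupling and how early-spring cloudiness
degrades the satellite signal.

## The method in brief

- **Green-up extraction.** Per pixel and 8-day period, EVI2
  (`2.5·(NIR−Red)/(NIR+2.4·Red+1)`) is the mean of the cloud-free looks.
  A penalized regression spline (GCV smoothing) is fitted per pixel-year
  and the green-up date is the day of maximum first derivative — the
  fastest greening, a proxy for bud-burst.
- **Nestbox green-up.** Bilinear interpolation over the four nearest
  pixel centres, each weight multiplied by the pixel's woodland
  fraction and renormalized.
- **Breeding analysis.** Laying dates back-counted from clutch counts
  (one egg/day), 30-day first-brood filter; linear mixed models with
  green-up split into between-year (annual mean) and within-year
  (deviation) components, random intercepts for year and nestbox.
- **Synchrony landscape.** Per-pixel across-year correlation between
  mean laying and pixel green-up; attempt-weighted regressions of that
  correlation on canopy/understory composition; Welch comparison of
  species; Mantel correlograms for spatial structure.
- **Cloud-window scan.** Annual laying-vs-green-up correlations
  regressed on mean cloud fraction over all 91 windows of 3–15 8-day
  periods in the first 120 days of the year, ranked by |r|.
- **Synthetic data.** A generator produces every input (grid, habitat,
  nestboxes, reflectances, cloud, breeding records, caterpillar
  half-fall dates) from known ground truth, so the whole pipeline is
  testable offline.

## Worked example

Simulate a small woodland and run every stage:

```r
library(phenosync)
dir <- file.path(tempdir(), "demo")
cfg <- pipeline_config(dir, seed = 11, min_years = 4,
  sim = list(grid_rows = 6, grid_cols = 6, n_nestboxes = 80, n_years = 6))
run_stage("all", cfg)

ws <- read.csv(file.path(dir, "out", "window_scan.csv"))
ws[which(ws$rank_abs == 1 & ws$species == "great_tit"),
   c("start", "length", "slope", "r", "p")]
#>    start length        slope          r          p
#> 72     8      4 -0.008785512 -0.7759279 0.06968731
```

The top-ranked cloud window (periods 8–11) has a negative slope:
cloudier springs, weaker apparent bird–vegetation synchrony, because
green-up estimates rest on fewer clear looks. The individual-level
mixed model (full covariate set) for the same run:

```r
fits <- jsonlite::read_json(file.path(dir, "out", "model_fits.json"),
                            simplifyVector = TRUE)
as.data.frame(fits$great_tit.full$coefficients)
#>              term     estimate           se          t          p
#> 1     (Intercept) -6.398097601 14.349583396 -0.4458734 0.65568869
#> 2       gu_within  0.064466792  0.068831030  0.9365949 0.34896697
#> 3      gu_between  0.212144341  0.129647904  1.6363114 0.10177444
#> 4        altitude  0.032596831  0.025011846  1.3032557 0.19248748
#> 5   edge_distance  0.008692147  0.004890916  1.7772023 0.07553497
#> 6 oak_density_75m -0.097427824  0.047912594 -2.0334492 0.04200716
```

`gu_within` is the days of laying shift per day of *local* green-up
deviation from the annual mean (the generating value here is 0.02; at
this toy scale the SE is wide), `gu_between` the response to the annual
mean itself. At the default full scale (11×11 pixels, 13 years,
1207 boxes) the within-year coefficient is recovered with SE ≈ 0.01.
Annual-scale output for the same toy run: green-up vs caterpillar
half-fall r = 0.805 (n = 6 years), green-up vs mean laying r = 0.605.

A command-line wrapper is installed with the package
(`inst/scripts/phenosync`):

```sh
Rscript inst/scripts/phenosync all --config config.yaml --seed 11 --verbose
```

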