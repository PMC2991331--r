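# ladscape

Analysis of DamID tiling-microarray tracks of nuclear-lamina (NL)
interaction and insulator-protein binding, as produced for the *Drosophila*
genome: probe-level log2(Dam-fusion/Dam-only) ratios go in; lamina-associated
domains (LADs), insulator binding peaks, border-aligned meta-profiles,
permutation enrichment statistics, motif hits and differential-NL summaries
come out — all as tidy tibbles that chain with the pipe.

## Who this is for

Chromatin and nuclear-organization groups working with DamID (or DamID-like)
probe tracks who need the full published analysis chain as reusable,
tested functions rather than one-off scripts: domain calling, peak calling,
meta-profiles across aligned domain borders, interval enrichment tests, and
the differential analysis after perturbing an insulator protein.

## The methods at the core

* **LAD calling** by a sliding edge filter: the score at probe *i* is the
  difference of mean log2 ratio between the half-window right of *i* and the
  half-window ending at *i* (window 199 probes). Transitions with
  |score| > 0.3 are paired into domains, kept when ≥ 70 % of enclosed probes
  have a positive running-median(5)-smoothed ratio.
* **Peak calling**: running mean of 5 probes, a 7-probe least-squares-slope
  derivative, apices at +→− sign changes, and per-probe one-sample
  empirical-Bayes moderated *t* tests (variance shrunk toward a
  moments-matched prior), BH-adjusted; a peak needs ≥ 3 probes with
  adjusted p < 0.005 in its support.
* **Border alignment**: data are mapped to coordinates relative to the
  nearest LAD border (positive inside), right borders mirrored, each datum
  used once (bounded at domain and gap midpoints); profiles are running
  medians over fixed fractions of the data, peak densities per 10-kb window
  per border, or binned coverage fractions.
* **Enrichment**: permutation tests that re-place peak centers uniformly in
  the probed span per chromosome, `p = (1 + k)/(N + 1)`; Fisher exact
  association tests; interior-window occupancy; co-binding classification.
* **Motif scanning**: PWM relative matching score
  `(S − S_min)/(S_max − S_min)` per window, both strands, thresholds 0.85
  or 0.99.
* **Differential NL interaction**: per-LAD mean change after
  knockdown/overexpression, LAD classes by peak density (none / any / top
  quarter), Wilcoxon rank-sum comparisons, and change-versus-peak-distance
  profiles.
* **Synthetic data**: a seeded generator planting LADs, peaks (border-
  proximal at −4 kb, interior at +40 kb, uniform), replicate noise and
  localized perturbation effects, with full ground truth emitted.

## Worked example

Simulate a two-chromosome genome with 20 planted LADs and 100 insulator
peaks, then run the pipeline:

```r
library(ladscape)
library(dplyr)

cfg <- sim_config(chrom_lengths = c(chr2L = 4e6, chr2R = 4e6),
                  n_lads = 20, lad_size_meanlog = log(1.2e5),
                  lad_size_sdlog = 0.3, n_peaks = 100, seed = 7)
lay <- simulate_peaks(simulate_layout(cfg))

# NL interaction track -> LADs
lam   <- simulate_damid_replicates(lay, signal = "lamin", seed = 8)
track <- normalize_and_average(lam, loess_detrend = FALSE)
lads  <- call_lads(track)
lad_summary(lads, sum(cfg$chrom_lengths))
#> # A tibble: 1 × 6
#>   n_lads n_borders min_kb median_kb max_kb coverage_fraction
#>    <int>     <int>  <dbl>     <dbl>  <dbl>             <dbl>
#> 1     20        40   71.5      116.   187.             0.315
```

All 20 planted domains are recovered; the size quantiles and coverage
reflect the planted log-normal sizes. Insulator peaks next:

```r
ins   <- simulate_damid_replicates(lay, signal = "insulator", seed = 9)
peaks <- call_peaks(ins)
peaks
#> # A tibble: 98 × 7
#>   chrom  start    end center height n_significant_probes name
#>   <chr>  <dbl>  <dbl>  <dbl>  <dbl>                <int> <chr>
#> 1 chr2L  17693  19163  18469   1.84                    5 peak_00001
#> 2 chr2L  99013 100366  99564   1.93                    4 peak_00002
#> 3 chr2L 143663 144964 144477   1.62                    5 peak_00003
#> # ℹ 95 more rows
```

`center` is the apex probe center (bp), `height` the smoothed log2 ratio at
the apex, and the span covers the significant probes. Are these peaks
enriched inside LADs?

```r
spans <- tibble(chrom = c("chr2L", "chr2R"), start = 0, end = 4e6)
permutation_enrichment(peaks, lads, spans, n_permutations = 999, seed = 10)
#> Permutation enrichment test (98 peaks, 999 permutations, seed 10)
#>   observed: 46.9%  expected: 31.5%  enrichment p = 0.001
```

46.9 % of called peaks fall inside LADs versus 31.5 % expected by chance
(the LADs' share of the probed span), at the permutation floor p = 0.001 —
the generator plants 30 % of its peaks at +40 kb inside domains, and the
density profile localizes exactly that interior mode:

```r
dens <- peak_density_profile(peaks, lads, chrom_lengths = cfg$chrom_lengths)
dens[which.max(dens$value), ]
#> # A tibble: 1 × 3
#>   rel_bp value     n
#>    <dbl> <dbl> <int>
#> 1  36000   0.8    32
```

`plot_profile(dens)`, `plot_track(track, lads)` and
`autoplot()`/`tidy()`/`glance()` methods cover the common figures and
summaries. See the methods vignette (`vignettes/ladscape-methods.Rmd`) for
the models, parameter meanings and design decisions.

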