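---
title: "Calling lamina-associated domains and insulator peaks from DamID tracks"
author: "ladscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling lamina-associated domains and insulator peaks from DamID tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladscape)
library(dplyr)
```

## The measurement and its data model

DamID fuses DNA adenine methyltransferase (Dam) to a chromatin protein —
here a lamin, or an insulator protein such as SU(HW), CTCF, BEAF-32, DWG or
GAF — so that everywhere the fusion contacts DNA it leaves stable adenine
methylation. Hybridizing methylation-enriched DNA from the fusion and from a
Dam-only control onto a tiling microarray yields, per probe, a
log2(Dam-fusion / Dam-only) ratio: positive where the protein touched the
locus more often than expected from accessibility alone. In *Drosophila* Kc
cells the array tiles the major chromosome arms at a median probe spacing of
roughly 300 bp.

`ladscape` represents a track as a plain tibble — `chrom`, `start`, `end`
(0-based half-open) plus one numeric column per replicate — so every step
composes with dplyr verbs. Interval sets (domains, border regions, genes,
Polycomb domains) are tibbles of the same shape; GFF import/export converts
between the 1-based inclusive file convention and the internal half-open one.

## Preprocessing

`normalize_and_average()` follows the conventional two-color pipeline: each
replicate is loess-detrended against a covariate, median-centered, the
dye-swapped replicate is sign-corrected, and the replicates are averaged.
Two points were genuinely open and are settled here as package choices:

* **Loess covariate.** When per-channel intensities are available their mean
  log-intensity is the natural covariate (classic MA-plot detrending). For
  ratio-only tables the probe index along the array is used instead, which
  removes slow spatial/positional drift. Both are supported; the default is
  the probe index because the package's inputs are ratio tracks. The span
  defaults to 0.3 — wide enough that domain-scale biology (tens of probes)
  is not absorbed into the trend.
* **Dye-swap handling.** Swapped replicates are negated before averaging;
  the orientation is supplied explicitly by the caller (`dye_swap =`) since
  nothing in a ratio table identifies it.

Averaging two already-centered columns can leave a residual offset of order
1/n, so the averaged track is centered once more; this makes the
"median = 0" invariant exact.

## LAD calling: the sliding edge filter

Domains of elevated nuclear-lamina (NL) contact have sharp borders, so the
caller looks for transitions rather than for levels. The edge score at probe
*i* contrasts the mean log2 ratio of the `w` probes to the right of *i* with
the `w` probes up to and including *i*, where the total window is
`edge_window_probes = 199` (so `w = 99`, about 30 kb per half-window at
300-bp spacing). A step of height *h* therefore produces a score of exactly
*h* at the step and a linear decay away from it. The statistic is a plain
difference of half-window means — the simplest reading of an "edge filter",
and the one under which the transition threshold (0.3, in log2 units) has
the same units as the track.

Candidate up-transitions are local maxima of the edge score above +0.3,
down-transitions local minima below −0.3. Within a run of same-sign
transitions only the strongest (leftmost on ties) survives; each
up-transition is then paired with the next down-transition. The pair becomes
a LAD only if at least 70 % of the enclosed probes have a positive log2
ratio, evaluated after running-median smoothing over 5 probes — the same
smoothing under which the reported per-domain score (fraction of positive
probes) is defined; a flag switches to raw values. Domain boundaries are
placed at the genomic midpoint between the transition's extremum probe and
its neighbor in the transition direction, since the statistic cannot resolve
the border more finely than the inter-probe gap. Domains with fewer than 5
probes are discarded as degenerate.

Two properties worth knowing: calls are scale-equivariant (multiplying
track and threshold by the same constant changes nothing), and raising the
threshold can only remove domains.

## Peak calling: derivative plus moderated per-probe significance

Insulator binding is point-like. The replicate-averaged track is smoothed by
a running mean of 5 probes; a local least-squares slope over a 7-probe
window serves as its derivative. An apex is a sign change of the derivative
from positive to non-positive. The slope is fitted by ordinary least squares
rather than finite differences because it stays well-defined and noise-
robust across the whole 7-probe window.

Significance is per probe: a one-sample moderated *t* on the replicate
values, with the per-probe variance shrunk toward a prior estimated by
moments matching on the log sample variances across all probes (the
standard empirical-Bayes construction; with two replicates this shrinkage is
the entire value of the test). The test is one-sided — DamID peaks are
defined by enrichment — and Benjamini–Hochberg adjusted across all probes.
When the log-variance spread carries no excess over its sampling noise the
prior degrees of freedom become infinite and the test falls back to a
pooled variance. A peak is reported when its support — the maximal
contiguous run of positively-smoothed probes containing the apex — holds at
least 3 probes with adjusted p < 0.005. The threshold is applied to
adjusted p-values by default; a flag applies it to raw p-values, since the
original description can be read either way.

One guard is not in the verbal recipe but is needed in practice: within a
single support run, residual noise on one bump can produce several
derivative sign changes a few probes apart, which would duplicate the call.
Apices closer than the derivative window (7 probes) to a stronger apex in
the same run are therefore suppressed. Genuine double peaks farther apart
than that are kept.

## Border-aligned meta-profiles

Profiles across domain borders pool all borders after mirroring: each
datum's coordinate is taken relative to its nearest border, positive inside
the domain, with right-border data reflected so "inside" points the same
way everywhere. A datum belongs to a border only up to the midpoint of its
domain (inward) and the midpoint of the adjacent gap (outward), so nothing
is counted twice. The flank before a chromosome's first domain is bounded
by half that terminal gap; the flank after the last domain is bounded only
when the chromosome length is supplied.

Three profile flavors serve different figure types:

* `value_profile()` — running median over windows covering a fixed fraction
  of the aligned points (5 % for border alignments, 10–20 % for
  perturbation analyses). Emitting the window's median coordinate along
  with its median value keeps the x-axis honest where point density varies.
* `peak_density_profile()` — aligned peak counts in a sliding 10-kb window
  on a 1-kb grid, divided by the number of borders. A literal per-border
  median count is available (`literal_median = TRUE`) but is almost always
  zero at realistic peak densities (~3,000 peaks over ~800 borders), so
  the per-border mean is the default reading of a "median number of peaks
  per window" axis.
* `coverage_profile()` — per-border base-level coverage fraction of an
  interval set in 1-kb bins, median across borders (for gene-coverage
  style panels).

Alignment to peaks (`peak_relative_coords()`) uses the same idea with
signed distances and regions bounded halfway to the neighboring peak.

## Enrichment statistics

`border_region_set()` materializes the 10-kb regions just outside each
border, truncating facing regions at the midpoint of narrow gaps and
clamping at chromosome starts. Enrichment of a peak set in any region set
is tested by permutation: peak centers are re-placed uniformly within the
probed span of each chromosome, preserving per-chromosome counts (this
guards against chromosome-composition artifacts), and
`p = (1 + k) / (N + 1)` counts permutations at least as extreme in the
tested direction. The expected fraction is reported as the permutation
mean, which converges to the regions' share of the probed span.
Whether the original analysis preserved inter-peak spacing is unknowable
from the text; uniform re-placement is the documented default. Associated
helpers cover the interior-window occupancy (peaks 35–45 kb inside borders
of domains with half-size ≥ 45 kb), the Fisher exact association between
border and interior binding, pairwise-distance histograms, and co-binding
classification of one factor's peaks by another factor's mean track level
(below 1.0 = "without", above 1.5 = "with").

## Motif scanning

Count matrices become log-odds PWMs against a uniform background with a
pseudocount of 0.25 per base (the scoring framework names no background
model; uniform is the neutral choice). A window's relative score rescales
its summed log-odds between the matrix's worst and best attainable sums, so
thresholds (0.85 for CTCF/SU(HW)-class motifs, 0.99 for GAF) are
comparable across matrices. Both strands are scanned, reverse-strand hits
are reported at forward coordinates, windows containing N score as missing,
and overlapping hits are kept — the profiles these hits feed are
insensitive to overlap, and thinning would discard information.

## Differential NL interaction

A perturbation experiment (knockdown or overexpression) yields a treatment
track and a control track on the same layout; their per-probe difference is
the change in NL interaction. Per-domain changes are means over enclosed
probes (median by option). Domains are stratified by insulator peak count
and density: none, at least one, and the top quarter by peaks-per-bp
(ties included upward so at least a quarter qualifies). Classes are
compared with the two-sample Wilcoxon rank-sum test — the classes are
disjoint domain sets, so the rank-sum (not signed-rank) variant is the
right reading. The change as a function of distance to the nearest peak is
a 10 %-window running median of probe deltas against |distance|, computed
separately for peaks inside domains, in border regions, and outside.

## The synthetic-data generator

Every pipeline stage is exercised on generated data with emitted ground
truth. The generator's defaults are the study conditions, chosen once:

* probe grid with uniform spacing jitter, median 300 bp; probes are 60-mers;
* log-normal domain sizes with a 90-kb median, placed without overlap;
  two-level signal +1.0 inside / −1.0 outside (log2 units), borders
  softened over ±2 probes so edge placement is not trivially exact;
* per-replicate i.i.d. Gaussian noise, sd 0.5 — at the two-level signal and
  40 % domain coverage this puts the inter-replicate Pearson correlation
  near 0.79, inside the concordance regime reported for replicate DamID
  experiments (~0.77);
* insulator tracks: background −0.5 with Gaussian bumps (sd 3 probes)
  rising to an apex of 2.0 at planted peaks. The negative background
  reflects depletion of the fusion signal away from binding sites and
  keeps positive-signal support regions local to peaks;
* planted peaks fall in three classes — 4 kb outside borders, 40 kb inside
  (both with 500-bp jitter), and uniform — drawing border/interior slots
  without replacement and keeping at least 5 kb between peaks so that the
  planted truth is resolvable by any caller;
* perturbation effects are localized at intra-domain peaks, either
  exponential (`amplitude * exp(-d / 5 kb)`, matching "strongest within
  ~5 kb, extending past 10 kb") or a plateau (full amplitude to 5 kb, zero
  by 15 kb). The plateau shape is what the differential-recovery checks
  plant, because a 10 %-distance-window median can recover a plateau's
  amplitude but necessarily under-reads a point-wise exponential maximum.

What the generator deliberately does not model: dye chemistry, GC and
restriction-fragment (GATC) bias, spatially correlated noise, and copy-number
structure. Tests passing on this generator therefore demonstrate
algorithmic correctness and calibration — not robustness to every artifact
of real arrays.

A deterministic companion, `synthetic_lad_catalog()`, builds a genome-wide
synthetic domain catalog at published summary conditions — 412 domains,
log-normal sizes with median 90 kb clamped to 7–700 kb, total length equal
to 40 % of the release-4 major arms — by taking log-normal quantiles and
solving the spread so the total hits the coverage target. It is packaged as
`inst/extdata/synthetic_table_s1_lads.gff` and is synthetic: only its
summary statistics, not its positions, are meaningful.

## Numerical choices and degenerate inputs

* Running windows shrink symmetrically at chromosome ends; missing values
  are excluded from window statistics, and an all-missing window is missing.
* Smoothing and derivatives never cross chromosome boundaries.
* Edge scores are missing wherever either half-window is incomplete; a
  chromosome shorter than the window yields all-missing scores and a
  warning.
* Zero-variance probes: if every probe variance is zero the moderated test
  warns and pools; single zero-variance probes are simply shrunk.
* Ties in the density quartile go upward (into the top class); ties in
  same-sign transition runs go to the leftmost probe.
* Points exactly on a region start are inside; on a region end, outside
  (half-open convention everywhere internally).
* Degenerate Fisher tables (an empty margin) return p = 1 with a warning
  rather than erroring mid-pipeline.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the pipeline at sizes a
laptop handles in seconds to a couple of minutes per stage: 8–24 Mb of
simulated genome (about 27,000–80,000 probes), 50 planted domains for the
domain-recovery check, 100 planted peaks for the peak-recovery check, 200
null datasets of 100 peaks each (199 permutations apiece) for the
permutation-calibration check, and 120 domains with 160 peaks for the
differential analysis. These sizes were chosen so that Monte-Carlo noise on
each reported rate is small relative to the acceptance bands.

## Known limitations

* The edge filter's statistic is a documented package choice; the original
  human-data implementation it descends from may have scaled its statistic
  differently, which would shift the meaning of the 0.3 threshold.
* With two replicates the moderated test leans heavily on the prior; heavy-
  tailed probe noise would misestimate it.
* The permutation null ignores probe-density variation within the probed
  span (peaks are re-placed uniformly in base pairs, not in probes).
* Motif scanning supports zero-order (uniform) backgrounds only.
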