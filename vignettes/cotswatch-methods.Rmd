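---
title: "Methods: citizen-science surveillance of crown-of-thorns starfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: citizen-science surveillance of crown-of-thorns starfish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotswatch)
```

## The surveillance problem

Crown-of-thorns starfish (COTS, *Acanthaster* spp.) are coral predators with
boom-and-bust population cycles. Outbreaks can kill most of the coral at a
site within months, yet they are patchy, ephemeral and spread across reef
systems far too large for professional monitoring alone — especially in
small Pacific island countries. A pragmatic response is a citizen-science
workflow: anyone who sees starfish files a short standardized report; a
moderator screens the stream; reports are triaged by abundance; and
candidate outbreak sites are verified with standardized underwater visual
census (UVC) before management acts.

`cotswatch` implements that workflow end to end: report validation and
ingestion, abundance categorization and triage, quadrat-based analysis of
what each observer class contributes, three-level classification of
verification surveys, and a reef/observer simulator so every stage can be
exercised at desk scale.

## The report form and its validation

A report mirrors a twelve-field online form: observer identity and contact,
date, a single map-click position (WGS84 decimal degrees), activity context
(snorkeling / scuba / other), depth range, an abundance entry, and optional
detail fields (swim duration, distance covered, juveniles seen, live coral
cover, feeding scars, survey-method note). Identity, contact, date,
position, context and abundance are mandatory; `parse_report()` rejects a
record that lacks any of them, has coordinates off the globe, or is dated in
the future. Every new report starts in `moderation = "pending"`, and
`moderate()` enforces a one-shot accept/reject transition: only accepted
reports enter any analysis.

Abundance entries may be quantitative (`"10"`), semi-quantitative ranges
(`"2-5"`), or qualitative (`"dozens"`). `parse_abundance()` normalizes all
three to a representative count:

* ranges take the midpoint rounded **down** — a deliberately conservative
  attribution;
* qualitative terms go through an editable mapping whose defaults are
  `several` = 5, `dozens` = 24, `large aggregation(s)` = 150,
  `hundreds` = 300. The defaults place each term near the middle of the
  abundance band its everyday meaning suggests; any count above 100 is
  band-equivalent, so the exact value of `large aggregations` is not
  load-bearing. Projects can replace the table wholesale via the run
  config;
* unknown terms raise a classed error so ingestion flags the report for
  moderation instead of guessing. These flagged reports are counted but
  excluded from category statistics, which is why an analysis n can sit a
  few reports below the ingested total;
* zero counts are valid absence records; they are accepted but excluded
  from abundance categorization, which covers observation reports of COTS
  only.

Observer typology: research and government stakeholders are professional;
private individuals non-professional; NGO and business observers are
professional only when flagged as trained, because trained volunteers are
the only professional pathway for those groups. The mapping is a plain
named vector and can be overridden.

## Abundance scale and triage

Counts map onto four categories that partition the positive integers:
single (1), low aggregation (2–10), intermediate aggregation (11–100), and
potential outbreak (> 100 per observation). Management priority is
two-level: at most ten starfish is low priority; more than ten marks a
candidate verification site. The two scales are consistent by construction
— elevated priority is exactly the upper two categories — and the test
suite scans every count up to 10^4 against an independent interval oracle
to keep it that way.

Observer-class comparisons use a plain Pearson chi-square on the 2 × 4
class-by-category table, expected counts from the margins, no continuity
correction: with samples in the hundreds and four categories, Yates'
correction would only bias the statistic downward. Categories empty in both
classes are dropped before testing so the degrees of freedom reflect the
occupied table.

## The quadrat grid

Detection range is measured on equal 5 km × 5 km quadrats. Positions are
projected with a local equirectangular projection about a per-country
anchor: `x = R·cos(lat₀)·Δlon`, `y = R·Δlat` in radians with R = 6371 km.
This is not an equal-area projection, but over the ≤ 0.5°-latitude spans a
country grid covers here the cell-area distortion is far below 1% (the test
suite checks projected distances against haversine within 1%), and it keeps
the package dependency-light. The anchor is embedded in every output's
metadata so grids are reproducible.

Cells are half-open squares `[x, x+s) × [y, y+s)`: a point exactly on an
edge belongs to the north-east cell. Indexing is `floor(offset / s)` with a
one-part-in-10⁹ tolerance so that points constructed exactly on an edge do
not fall a cell short through floating-point jitter.

Per quadrat we record report counts and occupancy per observer class plus
detection-band counts (single = 1, aggregation = 2–100, potential outbreak
> 100 — the bands used to summarize what each class detects).
`contribution_analysis()` then reports range size per class and combined,
the percent range increase of non-professionals over professionals
(rounded to the nearest integer: 116 vs 91 quadrats gives 27.47 → +27%),
mean observation density (reports per occupied quadrat), and the band
counts. Report counts per occupied quadrat are compared with a two-sided
Mann-Whitney U test. The implementation enumerates the exact null
distribution for pooled samples of at most 20 — exhaustive enumeration is
valid under ties, where the classical exact tables are not — and otherwise
uses the normal approximation with tie-corrected variance and no continuity
correction. On tie-free samples it agrees with `stats::wilcox.test` on both
paths, which the tests verify.

## Verification surveys and the three-level classification

Two UVC methods are supported. Belt transects (100 m² by default; the
simulator realizes them as 50 m × 2 m) yield densities directly:
`count / area × 10⁴` ind·ha⁻¹. Timed swims yield an abundance index;
density equivalents use the area actually scanned, distance × an empirical
2 m path width — so 5 COTS on a typical 250 m ten-minute swim is exactly
100 ind·ha⁻¹.

Densities classify on a conservative three-level scale anchored at the two
threshold families recurrent in the outbreak literature: below 15 ind·ha⁻¹
non-outbreak, 15–100 potential outbreak, above 100 confirmed outbreak. The
ten-minute-swim equivalents are 0–1 / 2–5 / > 5 COTS per swim. Both
potential bands are closed on both ends, matching the printed threshold
table; the two scales are an empirical lookup, not a single linear
conversion (they agree exactly at the 5-per-swim ↔ 100 ind·ha⁻¹ calibration
point and need not elsewhere). Partition scans over a fine density grid and
all swim counts to 1000 guard both scales.

Site aggregation: swims are first rescaled linearly to ten-minute
equivalents; each method's **mean** is classified; and the site takes the
more severe of the two method levels. Means were chosen over peaks because
a single dense aggregation under one transect would otherwise flip a site;
peaks are still reported per site, and the severity-max rule keeps a site
from being downgraded by its least sensitive method. Standard errors use
the n − 1 denominator. `summarize_sites()` pools per-method means across
sites weighting each site equally (its input is site-level statuses, so
survey-weighted pooling is intentionally out of reach there).

## The simulator

`simulate_population()` generates starfish as a homogeneous Poisson
background superposed with a cluster process of Thomas type: each supplied
cluster center receives a Poisson(μ) number of starfish placed uniformly in
a disc. The disc radius defaults to 25 m, reflecting the tens-of-meters
patch scale at which real aggregations have been observed to occupy a
~50 m reef section while the surrounding reef stays at background density.
Offspring landing outside the reef are redrawn inside their disc, so the
expected total is exactly `λ_bg·A + Σμ` (Campbell's formula), which a
200-seed Monte-Carlo check holds to within three standard errors.

`simulate_belt_transects()` and `simulate_timed_swims()` place survey
rectangles uniformly in position and orientation (rejection-free: centers
are drawn from the region where the rectangle fits). Transects have perfect
detection; swims thin the corridor count binomially with a detection
probability, so a swim at `detect_p = 1` is geometrically identical to a
belt of the same dimensions — a reduction the tests exploit.

`simulate_reports()` emulates the two observer classes: professionals draw
positions around a few project zones; volunteers uniformly over the whole
reef, giving them the broader spatial spread that drives the
range-increase result. A reported count is the number of simulated starfish
within a 50 m encounter radius, perturbed by multiplicative lognormal
perception noise (σ = 0.3 by default — miscounting is plausibly
multiplicative, and the parameter is exposed); a configurable fraction of
entries is rendered as qualitative terms. All observer-behaviour parameters
are declared assumptions, not field estimates: no quantitative observer
data exist to fit them.

What the simulator deliberately does **not** emulate: larval dispersal and
outbreak initiation, temporal boom-and-bust trajectories, depth effects and
day/night detectability differences, misidentification, and reef-polygon
geometry (the grid accepts an optional extent, not a reef mask). Passing
tests therefore demonstrate the pipeline's arithmetic and statistical
behaviour on data with the assumed spatial structure — not that real report
streams have that structure.

## Randomness, determinism, and problem sizes

Every stochastic operation takes an explicit integer seed; `run_pipeline()`
derives per-stage seeds from the run seed by fixed offsets, and identical
config + seed reproduces outputs byte for byte (checked on written files).
Monte-Carlo tests use 200 replicates for estimator-recovery and test-level
checks and 1000 replicates for the patch-missed-by-77-transects scenario,
sizes at which the checked expectations hold comfortably within three
standard errors while the full suite runs in under a minute.

## Known limitations

* The qualitative-term vocabulary is small; unknown terms are flagged, not
  inferred.
* The equirectangular grid distorts at high latitudes; anchor per country.
* The three-level thresholds are invariant, while sustainable density
  genuinely varies by reef; thresholds are therefore configurable but the
  defaults should be read as conservative screening values.
* Whether a real programme's site classifications used means, maxima or
  expert judgment is not recoverable from summary percentages alone; the
  severity-max-of-means rule here is a documented package choice.
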