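# cotswatch

Citizen-science surveillance and triage of crown-of-thorns starfish (COTS,
*Acanthaster* spp.) outbreaks.

COTS are coral-eating starfish whose boom-and-bust outbreaks can destroy
most of the coral at a reef in months. Monitoring them at country scale is
beyond the budget of most Pacific island management agencies, so a
practical workflow is participatory: snorkelers, divers, fishers, NGOs and
agencies file short standardized observation reports; the stream is
moderated, categorized and triaged; and candidate outbreak sites are
verified with standardized underwater visual census (UVC) before removal
campaigns are launched. `cotswatch` is that workflow as an R package, for
reef managers and the analysts supporting them.

## What it computes

* **Report model** — validation and ingestion (CSV / GeoJSON) of
  standardized reports: mandatory observer/date/position/context/abundance
  fields, WGS84 positions, one-shot moderation, and parsing of
  quantitative (`"10"`), range (`"2-5"`, midpoint rounded down) and
  qualitative (`"dozens"`) abundance entries through an editable term
  table.
* **Abundance triage** — the four-level scale (single = 1, low
  aggregation = 2–10, intermediate = 11–100, potential outbreak > 100
  per observation), the two-level priority rule (≤ 10 → low priority,
  > 10 → candidate verification site), stratified category summaries and a
  Pearson chi-square comparison of professional vs non-professional
  observers.
* **Spatial grid** — equal 5 km × 5 km quadrats under a local
  equirectangular projection; occupancy, range size (quadrats with ≥ 1
  report), mean observation density per observer class; percent range
  increase from combining classes; Mann-Whitney comparison of per-quadrat
  report counts (exact enumeration for small samples, tie-corrected normal
  approximation otherwise).
* **Survey classification** — belt-transect densities
  (count / area × 10⁴ ind·ha⁻¹), timed-swim area via distance × 2 m path
  width, and the three-level outbreak scale: < 15 / 15–100 / > 100
  ind·ha⁻¹, equivalently 0–1 / 2–5 / > 5 COTS per ten-minute swim; sites
  aggregate by classifying each method's mean and taking the more severe
  level.
* **Simulator** — seeded reef populations (Poisson background + Thomas-type
  clusters with uniform-disc offspring), belt-transect and timed-swim
  sampling, and two-class observer report streams, so the full pipeline
  runs without field data.

## Worked example

```r
library(cotswatch)

# A 20 x 15 km reef: sparse background plus two dense aggregations
reef <- simulate_population(
  extent = c(0, 20000, 0, 15000), background_intensity = 4,
  clusters = data.frame(x = c(6000, 15000), y = c(6000, 9000),
                        radius = 50, mu = c(2000, 3500)),
  seed = 42)

reports <- simulate_reports(reef, anchor = c(166.4, -22.3), seed = 43)
summarize_categories(reports)
#> # A tibble: 4 × 3
#>   level                        n    prop
#>   <ord>                    <int>   <dbl>
#> 1 single                      13 0.106
#> 2 low_aggregation            109 0.886
#> 3 intermediate_aggregation     1 0.00813
#> 4 potential_outbreak           0 0
```

Most simulated reports fall in the ≤ 10-starfish categories — the
low-priority share a manager can deprioritize when resources are thin.

```r
spec <- grid_spec(166.4, -22.3, cell_km = 5)
contribution_analysis(grid_summary(reports, spec))[
  c("range_professional", "range_non_professional", "range_increase_pct")]
#> $range_professional
#> [1] 4
#> $range_non_professional
#> [1] 12
#> $range_increase_pct
#> [1] 200
```

Zone-bound professionals covered 4 quadrats; opportunistic volunteers
detected COTS in 12, a +200% range increase in this simulation — the
mechanism by which combining observer classes widens detection range.

```r
# Verify a flagged site with 20 belt transects and 10 timed swims
patch <- simulate_population(c(0, 1000, 0, 500), background_intensity = 0,
  clusters = data.frame(x = 500, y = 250, radius = 100, mu = 1500), seed = 7)
surveys <- rbind(simulate_belt_transects(patch, 20, seed = 44, site_id = "VU01"),
                 simulate_timed_swims(patch, 10, seed = 45, site_id = "VU01"))
classify_site(surveys)
#>   site_id              level n_transects density_mean density_peak n_swims swim_mean
#> 1    VU01 potential_outbreak          20           20          400      10       3.6
```

The site mean (20 ind·ha⁻¹ on transects, 3.6 per ten-minute swim) lands in
the 15–100 ind·ha⁻¹ / 2–5 per-swim band: a *potential* outbreak needing
further monitoring, even though one transect crossed the aggregation at
400 ind·ha⁻¹.

A thin subcommand CLI wrapping the same functions ships in
`inst/cli/cotswatch.R` (`simulate`, `ingest`, `triage`, `grid`,
`classify-surveys`, `run`).

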