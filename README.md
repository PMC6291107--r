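# perchwatch

Analysis of RFID detection streams from PIT-tagged hummingbirds at
instrumented nectar feeders.

Feeding stations fitted with RFID antennas log a timestamped read of a
bird's passive integrated transponder (PIT) tag every 10 s while the bird
is in range. perchwatch turns those raw read streams into the quantities
behavioural ecologists care about:

* **Visits** — a visit is a maximal run of one bird's reads at one
  station with every inter-read gap ≤ 11 s; its duration is last read −
  first read, so single-read ("transient") visits have duration 0.
* **Visitation metrics** — per-bird visit counts, total and proportional
  time at feeders, detection latency, primary/secondary/tertiary feeder
  rankings, cross-site movement, and Kruskal–Wallis / Fisher's exact
  group comparisons.
* **Diel rhythms** — seasonal mean-hourly activity profiles, the
  Rayleigh test of circular uniformity on visit clock times
  (R̄ = |Σe^{iθ}|/n, Z = nR̄²), and nocturnal-activity flagging
  (22:00–04:00 window).
* **Contact networks** — pairwise interactions between visits at one
  station (TRANSIENT when the between-visit gap < 11 s, LONG when the
  interval overlap > 11 s), a weighted undirected contact network, degree
  and normalized betweenness centralities, and node-label permutation
  regressions of centrality on sex and age (add-one permutation
  p-values).
* **Apparent survival** — monthly encounter histories, a
  covariate-capable Cormack–Jolly–Seber likelihood
  (φ and p logit-linked to season/sex/age terms, with the standard χ
  never-seen-again recursion), AICc model selection in two steps
  (detection structure first, then survival), and monthly→annual
  conversion φ_annual = φ_monthly¹².
* **A synthetic colony** — a generator with full ground truth (rosters,
  true visit intervals, duty-cycled detection rendering, direct CJS
  process simulation) so every stage is testable without field data.

## Worked example

Simulate a small colony and run the whole pipeline from one config:

```r
library(perchwatch)

cfg <- colony_config(
  n_birds = list(ANNA = c(F_AHY = 10, F_HY = 10, M_AHY = 10, M_HY = 10)),
  sites = list(site2 = c("A4", "A5", "A8")),
  start = "2017-05-01", end = "2017-07-31",
  visit_rate = 10, phi_monthly = 0.9,
  p_detect = c(AHY = 0.95, HY = 0.6, UNKNOWN = 0.6),
  night_frac = 0.1, follower_pairs = 5)

bundle <- run_pipeline(run_config(simulate = cfg,
                                  survival_start = "2017-05",
                                  survival_occasions = 3,
                                  n_perm = 1000, seed = 42))
bundle
#> perchwatch report bundle
#>   37590 detections -> 24601 visits by 39 of 40 tagged birds (97.5%)
#>   interactions: 1059 | network: 39 birds / 389 edges
#>   survival top model: Phi(~1) p(~adult)

bundle$rayleigh
#> Rayleigh test: n = 24601, Rbar = 0.1002, Z = 247.127, p = 2.694e-108

bundle$primary_tally
#>   station_id n_primary_birds
#> 1         A4              16
#> 2         A8              13
#> 3         A5              10

head(bundle$permutation[, c("response", "term", "beta_observed", "p_perm")], 4)
#>      response  term beta_observed     p_perm
#> 1      degree  sexM   0.105405405 0.95304695
#> 2      degree ageHY  -3.694594595 0.05194805
#> 3 betweenness  sexM  -0.001541874 0.59540460
#> 4 betweenness ageHY  -0.006021748 0.04695305
```

Reading: 37,590 duty-cycled tag reads segment into 24,601 visits; 39 of
the 40 simulated birds returned to a feeder at least once (97.5%). The
Rayleigh test rejects circular uniformity of visit clock times (the
generator's diel mixture is bimodal at dawn/dusk). Station A4 is the
primary (most-visited) feeder for 16 birds. The permutation regression
finds no significant sex effect on degree; the apparent age effect is
expected here because hatch-year birds were simulated with lower monthly
detection. The two-step CJS model selection correctly picks
`Phi(~1) p(~adult)` — age-dependent detection, constant survival — the
structure the data were generated under.

Individual stages are plain functions on plain data frames:
`read_detection_log()` → `segment_visits()` → `summarize_birds()` /
`diel_profile()` / `detect_interactions()` → `build_network()` →
`centralities()` → `permutation_glm()`, and
`build_encounter_histories()` → `fit_cjs()` /
`model_selection_two_step()`.

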