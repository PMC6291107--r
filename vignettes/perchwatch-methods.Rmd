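---
title: "perchwatch: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perchwatch: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(perchwatch)
```

perchwatch analyses detection streams from RFID-instrumented hummingbird
feeders. This vignette is the package's own account of the models it
implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## 1. From tag reads to visits

A transceiver on its standard duty cycle logs the same tag at most once
every 10 s while the bird stays in antenna range. Timestamps are parsed
as **timezone-naive local clock time** (stored as UTC so daylight-saving
rules can never shift wall-clock hours): the diel analyses need the hour
the bird experienced, and feeder activity at "17:30" must mean 17:30 on
the local clock in every season.

`segment_visits()` groups each bird's reads per station and merges
consecutive reads whose gap is **at most 11 s** into one visit. The rule
is inclusive: an 11-s gap merges, a 12-s gap splits. With a 10-s duty
cycle, a bird continuously present yields gaps of 10–11 s, so the
inclusive threshold is what makes continuous presence a single visit.
Visit duration is last read minus first read; a single read gives
duration 0. Visits with duration under 10 s are called *transient* —
below the duty cycle's resolution, they are indistinguishable from
instantaneous stops and always recorded as 0 s. Consequences worth
keeping in mind:

* all durations are biased low by up to one duty interval (the time
  after the last read is unobservable);
* re-segmenting a rendered synthetic visit of true duration $d$ recovers
  $10\lfloor d/10\rfloor$, which the round-trip tests assert exactly;
* mean visit duration *includes* transients as 0 s. This is why a
  colony can show a mean visit duration of a few seconds while its
  non-transient visits average ~25 s.

Duplicate reads (same tag, station, second) collapse to one detection.
Visits are station-scoped; a bird cannot physically be at two stations
at once, so cross-station overlap is left to the validation report
rather than merged.

Per-bird summaries (`summarize_birds()`) define the observation span as
first-to-last detection and `proportion_time = total_time / span`; a
single-detection bird has span 0 and its proportion is defined as 0 and
flagged, never `NaN`. Because the printed duration range of a real
deployment can mix transient and non-transient conventions, summaries
report both the all-visit and the non-transient distributions (median
and mean are computed over all visits; `n_transient` lets the user
recompute either way).

## 2. Feeder ranking and group comparisons

`rank_feeders()` sorts each bird's stations by visit count (ties broken
lexicographically by station id so results are deterministic) and labels
ranks 1–3 primary/secondary/tertiary. Ranking uses visit *counts*, not
time: counts are robust to the duration truncation above.

Group comparisons use the tie-corrected Kruskal–Wallis H with the
χ²(k−1) reference distribution regardless of group size — the common
practice in this literature — via `stats::kruskal.test`; Fisher's exact
test for 2×2 tables sums hypergeometric probabilities of tables no more
probable than the observed one (`stats::fisher.test`). Both are thin
wrappers: the package deliberately does not reimplement standard tests,
but its test suite verifies them against hand rank-sum arithmetic and
full hypergeometric enumeration.

## 3. Diel profiles and the Rayleigh test

`diel_profile()` computes, for one season (winter = Dec–Feb, the other
seasons by the same meteorological convention), the mean and standard
error of visits per clock hour **across calendar days**, including
zero-visit days inside the data's span — so
`sum(hourly_mean) * n_days = n_visits` holds as an invariant. Activity
spans are reported both as daily means and as overall extremes, since a
single night visit should not silently redefine "active from".

`rayleigh_test()` maps visit start times to angles
$\theta = 2\pi t/86400$ and uses the classical statistic
$\bar R = |\sum e^{i\theta}|/n$, $Z = n\bar R^2$, with the standard
series approximation

$$p = e^{-Z}\Big[1 + \frac{2Z - Z^2}{4n} -
  \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\Big]$$

clamped to $(0, 1]$. The test is applied to **individual visit start
times** (one angle per visit), not to the 24 binned hourly means: the
binned phrasing found in field reports is ambiguous, and per-visit
angles give the test its standard sample size; a user can always bin
first and pass weighted angles if they want the other reading. One
caveat the acceptance run makes visible: a dawn/dusk mixture with peaks
~12 h apart is nearly antipodal on the 24-h circle, so $\bar R$ is small
(the first moments nearly cancel) and the Rayleigh test is not the most
powerful test against such symmetric bimodality — with tens of
thousands of visits it still rejects overwhelmingly, which is exactly
the regime of these data.

`night_activity()` flags visits starting in [22:00, 24:00) ∪
[00:00, 04:00] — inclusive at exactly 04:00:00, exclusive above.

## 4. Interactions and the contact network

Two different birds' visits at the same station interact when either

* the interval overlap ("co-mingling time") **exceeds 11 s** → LONG, or
* the gap from the earlier visit's end to the later one's start is
  **strictly below 11 s** → TRANSIENT.

A gap of exactly 11 s is no interaction. The two stated rules leave
overlaps in (0, 11] unassigned; perchwatch classifies them TRANSIENT,
keeping "long" faithful to "more than 11 seconds". All qualifying pairs
are emitted, not just time-adjacent ones — one long visit can interact
with several partners — and detection is symmetric in the input order,
with pairs canonicalized `bird_a < bird_b`.

`build_network()` sums co-mingling seconds into edge weights (purely
transient edges have weight 0 but still exist). Degree is the number of
distinct partners; betweenness uses **unweighted** shortest paths —
the field's verbal definition counts paths, not weights — normalized by
$(n-1)(n-2)/2$; a weighted variant (distance $1/w$, zero-weight edges at
distance 1) sits behind a flag for sensitivity analysis. igraph provides
the graph algorithms; the test suite checks betweenness against an
independent exhaustive simple-path enumeration on all graphs of ≤ 8
nodes it generates.

`permutation_glm()` regresses each centrality on dummy-coded sex and
age, then permutes the attribute rows jointly across nodes, keeping the
network fixed. The family is Gaussian OLS on raw centralities: with
permutation inference the family choice only affects the test statistic,
not the validity of the p-value. P-values use the add-one estimator
$p = (1 + \#\{|\beta^*| \ge |\hat\beta|\})/(1 + n_{perm})$, so $p = 0$
is impossible and $p \ge 1/(n_{perm}+1)$. Nodes with UNKNOWN attributes
are excluded by default (they can instead be kept as their own level);
a predictor constant across nodes yields `NA`, not a fake zero.
Force-directed layout is cosmetic and out of scope; `as_igraph()` hands
the graph to any layout the user likes.

## 5. Cormack–Jolly–Seber survival

`build_encounter_histories()` collapses the continuous detection stream
to monthly 0/1 samples — a deliberate, heavy reduction that buys the
standard CJS machinery. The tagging month is the release occasion and
counts as the first encounter (standard CJS conditioning on first
release); whether the tagging capture or only subsequent RFID reads
should define occasion 1 is not decidable from the data conventions
alone, and this choice is the one that uses all birds.

The likelihood is the classic conditional-on-release form. With
survival $\phi_{i,t}$ over interval $t$ and detection $p_{i,t}$ at
occasion $t+1$, a bird released at $f$ and last seen at $l$ contributes

$$\prod_{t=f}^{l-1} \phi_{i,t}\,
  p_{i,t}^{h_{i,t+1}} (1-p_{i,t})^{1-h_{i,t+1}} \times \chi_{i,l},
\qquad
\chi_{i,T} = 1,\;
\chi_{i,t} = (1-\phi_{i,t}) + \phi_{i,t}(1-p_{i,t})\chi_{i,t+1}.$$

Tests verify that, for every parameter value, these per-history
probabilities sum to one over all possible observation tails (brute
force, $T \le 6$) — the likelihood is a genuine probability model, not
just a formula. Emigration and death are confounded; $\phi$ is
*apparent* survival.

`fit_cjs()` puts logit links on both parameters with formulas over
`sex`, `adult` (AHY = 1) and `season` (winter = Dec–Feb; the interval's
*starting* month for survival, the occasion's own month for detection).
Numerical choices: coefficients start at 0 (probabilities 0.5), BFGS
with tight relative tolerance, SEs from the numerically differentiated
Hessian, real-scale estimates with delta-method SEs. Non-convergence is
reported, never silently accepted; linear predictors beyond ±10 on the
logit scale are flagged as boundary estimates (perfect redetection
drives $\hat p \to 1$, a flagged but valid ML outcome). Birds of
unknown sex/age are dropped from covariate models with a warning.

`aicc()` applies the small-sample correction $2K(K+1)/(ess-K-1)$. The
**effective sample size is the number of usable histories** (each bird
is released once). Capture–recapture software differs on this
convention; the choice is an argument, so users can pass total
detections or at-risk intervals instead. `model_selection_two_step()`
screens detection first (survival saturated with all three covariates),
then survival under the winning detection model, with the full null
included in both steps and Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$.

`annual_survival()` is $\phi^{12}$ — the compounding that turns a
monthly 0.76 into a startling annual 0.04, which is why transient
individuals matter for real deployments (a time-since-marking extension
is a natural next step; the design leaves the release-age hook open but
does not implement it).

## 6. The synthetic colony: a stated world

The generator's defaults are fixed to the conditions the analyses
assume, and are **not** tuning knobs:

| parameter | default | rationale |
|---|---|---|
| roster cells | 230 birds, 167/63 by species | published demographic margins |
| sites/stations | 3 sites, 1+3+3 stations | deployment layout |
| duty cycle | 10 s | transceiver setting |
| transient probability | 0.744 | 48,713 of 65,476 visits |
| non-transient duration | 11 s + Exp(mean 14 s), cap 615 s | long-visit mean ≈ 25 s, observed max 615 s |
| visit rate | 19 / bird-day | ≈ 65,476 visits / (141 birds × 24.6 detected days) |
| feeder preference | Dirichlet(13, 1.7, 0.3), permuted | targets ≈ 87/11/2% primary/secondary/tertiary shares |
| diel mixture | peaks 05:30 & 17:30, sd 1.5 h, weights 0.45/0.55 | dawn/dusk bimodality |
| monthly survival | 0.76 | top-model estimate |
| detection by age | AHY 0.91, HY 0.39 | top-model estimates |
| night-active fraction | 0.05 | 7 of 141 detected birds |

Only the exponential duration *family* is a generator convention (field
reports give means, not distributions), as are the Dirichlet
concentration and the per-season weight split; both are documented here
and fixed once.

Generator mechanics that matter for interpreting green tests:

* **Identifiability constraints.** Successive same-bird visits at one
  station are forced at least one duty interval plus 2 s apart, and
  diurnal birds are truncated out of the 22:00–04:00 window (their
  Gaussian tails would otherwise leak a handful of "night" visits per
  thousand). These make the true visit count and the nocturnal flag
  exactly recoverable, which the round-trip tests exploit. Real data
  offer no such guarantees.
* **Age-dependent detection** enters as a monthly Bernoulli
  activity gate per bird: in a month where the gate is off, the bird
  makes no feeder visits. This reproduces age-dependent monthly
  detection without modelling *why* hatch-year birds are detected less.
* **Interactions are emergent**, not simulated: they arise from
  overlapping independent visit processes. `follower_pairs` optionally
  plants same-site leader–follower pairs whose co-visits guarantee
  known LONG interactions for network tests.
* Not emulated: weather and phenology, territory structure, movement
  between sites (every simulated bird stays at its tagging site, which
  is what makes the 3-component community test exact), trap response,
  tag loss, and clock drift. A green end-to-end test establishes that
  the *pipeline* is correct under the stated world, not that the world
  is complete.

All generator output is deterministic given a seed; the pipeline
expands its single master seed through fixed per-stage offsets so adding
a stage never changes an earlier stage's stream.

## 7. Known limitations

* Durations and co-mingling times are quantized by the duty cycle;
  transient interactions are over-counted relative to truth (two single
  reads < 10 s apart may be a near miss, not a contact).
* The Rayleigh test's low power against antipodal bimodality (see §3).
* The CJS model ignores transients and assumes homogeneous detection
  within covariate classes; the monthly reduction discards most of the
  information in the continuous stream.
* The two-antenna comparison treats the side antenna as reference by
  convention; `merge_dedup` is available but changes visit counts
  slightly (1-s collapse window).
* One historical deployment quirk — a 2-minute duty cycle in the first
  months at one site — is handled by the same 11-s gap rule by default;
  the gap threshold is an argument precisely so sensitivity analyses
  can re-segment such periods differently.
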