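---
title: "Processing light-level geolocator tracks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing light-level geolocator tracks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glspipe)
```

# The estimation problem

An archival light-level geolocator stores twilight times (and here also
sea-surface temperature, SST) once per day; the bird must be recaptured to
read the tag. Position must be inferred:

* **Longitude** from the UTC midpoint of sunrise and sunset. Local apparent
  noon at the bird sits at `t_mid`; correcting for the equation of time
  (EoT) and converting hours to degrees gives
  `λ = −15°/h · (t_mid − 12 h + EoT)`. The midpoint is taken on the shorter
  arc so a twilight pair spanning local midnight is handled.
* **Latitude** from day length. With solar declination δ and a calibrated
  sun elevation angle *a* that defines "twilight" for the tag, the
  hour-angle equation `cos H = (sin a − sin φ sin δ)/(cos φ cos δ)` links
  day length `2H` to latitude φ. We invert it by bisection on
  φ ∈ [−85°, 85°].

Both use a low-precision NOAA-style solar ephemeris (declination good to
~0.01°, EoT to ~0.1 min over 1990–2100), far inside the error budget of the
method itself.

Two degeneracies are intrinsic. Near the equinoxes (|δ| small) day length is
nearly 12 h at every latitude, so the inversion is ill-conditioned; we flag
days with |δ| < 5° (about ±13 days around each equinox) as
`equinox_flagged` rather than using fixed calendar dates, because the flag
then tracks the actual conditioning. In continuous polar day or night there
is no twilight at all and the day yields a sentinel, not a position.

# SST latitude correction

The tag's minimum daily SST is compared with 8-day nighttime satellite
composites. Along the (fixed) twilight longitude — the profile is averaged
over the longitude cell and its two neighbours — we find the latitudes where
the meridional SST profile **crosses** the tag value, interpolating linearly
between grid rows; where the profile merely plateaus within the matching
tolerance (default 0.5 °C) without crossing, the plateau cells serve as
candidates. Among candidates, the one nearest the previous day's latitude is
taken (`source = "sst_corrected"`). The search is confined to ±15° of the
threshold latitude except on equinox-flagged days, which search the whole
grid — this is what lets the pipeline *retain* data through the equinox
windows instead of discarding a month of track. Longitude is never altered,
and a day with no tag SST or no candidate keeps its threshold estimate.

Two implementation choices deserve emphasis:

* **Crossings, not cells.** Snapping the matched latitude to the grid
  lattice quantises it (a full cell at coarse stacks), and combined with
  the nearest-to-previous rule it produced a systematic lag of roughly
  (tolerance ÷ gradient) degrees during sustained travel. Interpolated
  crossings remove both artefacts.
* **A 3-day matching window** (`sst_match_window = 3`; set 1 for strict
  single-day matching). The tag value matched is a centred running mean.
  With a realistic meridional gradient of ~0.3 °C/° and tag noise of
  0.3 °C, single-day matching leaves ~1.1° of latitude noise — enough to
  blur the stopover/travel boundary downstream. The windowed form is also
  closer to the windowed SST-correlation approaches long used for
  geolocator tags. For a field linear in latitude the window introduces no
  bias at constant travel speed, since the mean of the field over three
  positions equals the field at the mean latitude.

A High-Arctic colony sits in continuous daylight for part of the
deployment. Leading POLAR_DAY records — light consistent with continued
residency in the polar zone — are held at the known colony position
(`fixed_colony`), up to three days before the first twilight-resolved
record. The remaining gap lets the catch-up displacement spread over enough
days to clear the speed filter while still being credited to migration;
without this anchor the first ~2 weeks of a fast southbound departure are
silently absorbed into a low-rate gap.

# Track cleaning

**Speed filter.** "No more than 13.9 m/s sustained over 48 h" is
operationalised as the root-mean-square of implied speeds (great-circle
distance over actual elapsed time) from a position to every retained
neighbour within the 48-h window. The worst offender is removed and speeds
are recomputed, until no position exceeds the limit — so a single spike is
removed without dragging its neighbours out. A strict per-pair mode
(`strict_pairwise`) is available. Fixed colony positions are never removed.
The filter is idempotent by construction.

**Smoothing.** Each interior position is replaced by the 1:2:1 weighted
mean of its previous/current/next positions, computed simultaneously from
the *original* neighbours (order independence). Longitudes are averaged
after unwrapping about the current position, so antimeridian crossings
smooth to ±180°, never to 0°. Not smoothed, but still used as neighbours:
first and last positions, fixed colony positions, and positions whose
movement to either neighbour exceeds 4° longitude or 6° latitude
(`unsmoothed_jump`) — smoothing across a genuine relocation would
manufacture positional error.

# Stopover/travel segmentation

Daily movement is distance ÷ elapsed days, assigned to the later date, so a
multi-day gap cannot fake a travel day. The classifier is a two-state
machine starting in STOPOVER (the bird is at its breeding site): in
STOPOVER, when at least 3 days in the forward window of 5 anchored at the
current day exceed 100 km/d, the state becomes TRAVEL at the first
exceeding day in that window; the rule back is symmetric. Truncated windows
at the series end keep the same count requirement. Window anchoring and the
transition-effect day are not uniquely determined by the verbal rule; the
forward anchor with first-qualifying-day effect is the default and the
behaviour is pinned by an exhaustive equivalence test against a reference
machine on all 4,096 binary series of length 12.

The published workflow then screened the classification by hand for "burst"
days — 1–2 day relocations too short to trigger the window rule. The
automated surrogate applies the same *fast and far* judgement in both
directions:

* a 1–2 day run of fast STOPOVER days is relabelled TRAVEL when the
  flanking stopover centroids are more than `burst_factor × threshold`
  (default 200 km) apart;
* a 1–2 day TRAVEL run whose flanking stopover centroids are *closer* than
  that is a noise-triggered transition and reverts to STOPOVER;
* a travel-run edge day moving at less than half its run's mean daily rate
  reverts to STOPOVER. This targets a specific smoothing artefact: the
  1:2:1 smoother drags the stopover day adjacent to a travel leg about a
  quarter of the leg length (~90 km at 350 km/d), pushing it just over the
  100 km/d threshold. The criterion is self-scaling, so uniform genuine
  runs are untouched.

Without the last two rules, blurred edges and noise runs inflate travel-day
counts by roughly a fifth and bias travel speed low by ~10%.

# Wintering areas, phases and metrics

Winter positions are pooled per basin — each bird's terminal stopover
block, extended backward across travel interruptions of ≤2 days (burst
scale), restricted to the Southern Hemisphere — and a kernel density is
built in an Albers equal-area conic (spherical Snyder forms; South-America
and Africa presets, or data-driven standard parallels at the 1/6 and 5/6
latitude quantiles). The kernel is the quartic (biweight) with compact
support equal to the 200 km search radius, matching the GIS tools whose
"search radius" semantics this reproduces; the surface is normalised to
unit volume on a 10 km grid padded by one bandwidth. Occupancy contours are
highest-density regions: the threshold for level *p* captures the smallest
volume ≥ *p*/100, regions nest exactly by construction, and polygons follow
the isoline at the threshold (inverse-projected to WGS84 for GeoJSON
export). Membership tests for arrival detection use the thresholded cells
themselves, so the polygon and the test can never disagree.

Fall migration runs from departure (first TRAVEL day after the breeding
residency) to arrival (first STOPOVER day inside the basin's 50% contour);
later days are WINTER and excluded from migration metrics. Travel distance
sums adjacent-pair great-circle distances whose later day is a TRAVEL day
inside fall migration — stopover movement is excluded by definition — and
travel speed divides by travel days only. Welch's *t* compares basins;
one-way ANOVA with Tukey HSD compares seasons. The Welch statistic is
computed from the closed forms (and cross-checked against `stats::t.test`
in the tests); ANOVA and Tukey delegate to `stats::oneway.test`,
`stats::aov` and `stats::TukeyHSD` (the studentized-range distribution via
R's `ptukey`).

# The synthetic cohort: what it emulates, and what it does not

`sim_config()` encodes the study conditions: colony at 75.8° N, 96.3° W;
fall departures drawn 5 Aug–3 Sep; coastal great-circle waypoint routes of
~14,630 km (Pacific, via the Bering Strait to a Humboldt-like centre at
10° S, 85° W) and ~14,660 km (Atlantic, via Baffin Bay and West Africa to a
Benguela-like centre at 25° S, 10° E); per-bird travel speeds ~N(350, 35)
km/d truncated to [260, 480]; 3–5 en-route stopovers of 7–15 d (so total
fall duration centres near 84 d); an optional 1-day burst relocation of
300–500 km splitting one stopover (probability 0.3); and a wintering
residency of 40–60 d as a reflected random walk (step s.d. 45 km/d, hard
cap 95 km/d, radius 600 km) about the basin centre. Twilights come from the
forward solar model plus 4 min Gaussian noise per twilight (≈1° of
longitude); tag SST is the analytic field at the true position plus 0.3 °C
noise with 5% missing days. The default SST field is linear in latitude,
`T = 20.9 − 0.3·φ` °C plus a 1 °C seasonal cycle — strictly monotone (so
SST identifies latitude uniquely along a meridian), informative everywhere
the birds fly, and within the physical range over the occupied domain. A
bounded logistic profile is available; its realistic variant is near-flat
in the southern winter band, which is exactly the regime where SST-only
latitudes degrade.

By construction travel-day displacements exceed the 100 km/d threshold and
stopover/winter displacements stay below it (winter steps are capped at
95 km/d), so the generator's labels are a valid oracle for segmentation.
Three conditions follow the study's structure rather than free choice: the
winter walk is shared-centre (all birds' early-winter fixes pile up at the
basin centre, keeping every arrival point inside the 50% contour — per-bird
centre scatter or a seasonal range drift both push some arrival points into
the pooled-density tail and break arrival dating); the published hint that
~100 km/d is the *mean* winter daily movement is not reproduced literally,
because much of that figure is position error in real data and the oracle
invariant takes precedence; and route lengths were fixed once to the
reported ~14.6 Mm scale.

The generator does **not** emulate: wind drift or foraging loops; weather-
and shading-driven twilight error (real error is heavier-tailed and
day-to-day correlated, which makes our iid noise conservative for
variance-based checks but optimistic for outlier robustness); SST fronts,
clouds and upwelling structure (the field is smooth and monotone, so SST
matching here has no multi-modal ambiguity except where constructed);
tag failure modes other than clean truncation. Passing tests therefore
demonstrate correctness of the *algorithms* under the stated noise model,
not field performance on real tags.

# Numerical choices and degenerate inputs

* Sphere radius 6371.0 km everywhere; longitudes half-open [−180, 180),
  latitude +N; one position per UTC calendar day.
* Latitude bisection: 60 iterations on [−85°, 85°] (≈ machine precision);
  no bracketing sign change → polar flag, never an extrapolated value.
* Kernel evaluation accumulates per-point over its compact-support window
  only; volume renormalised at the end (guards accumulated round-off).
* Contour thresholds are taken fractionally below the cell value
  (`t·(1−10⁻⁹)`) so the isoline encloses the cells at the threshold.
* Empty tracks, all-missing SST grids, single-point KDEs, and tracks of
  fewer than three positions are all defined no-ops or flagged errors, not
  crashes; a bird failing mid-pipeline is recorded and skipped.
* Percent-valid is positions surviving the speed filter over
  twilight-resolved positions: polar blackout days yield no location at all
  and belong in neither numerator nor denominator.

# Test design and problem sizes

The suite validates each stage against independent oracles: published
ephemeris values; zero-noise forward/inverse round trips (200 random
positions, recovery within 0.2° longitude / 0.5° latitude away from the
equinox window); an exhaustive single-removal search for the speed filter;
the 4,096-sequence enumeration for the classifier; `geosphere` for
distances; closed-form Welch/ANOVA identities and a 2,000-replicate null
calibration of the Welch test's type-I error. End-to-end checks run cohorts
of 20 birds (18 Pacific, 2 Atlantic — the study's basin ratio) over three
seeds for segmentation accuracy and schedule recovery, and a 10-bird cohort
for conservation and speed recovery; these sizes give stable averages while
keeping the full suite around a minute. The 50%-contour capture fraction is
asserted on 2,000 iid draws from the winter spatial law (and on an iid
bivariate normal for the KDE itself): daily fixes of any sub-100 km/d
winter process are necessarily autocorrelated at the 200-km bandwidth
scale, which inflates *in-sample* capture for any generative design — the
contour-volume property under test is a property of the estimator, so it is
tested on independent samples.

# Known limitations

* Threshold latitudes assume a correctly calibrated sun angle; the angle is
  configurable but no in-habitat calibration procedure is included (raw
  light curves are out of scope — the pipeline starts from twilight times).
* SST matching is single-profile per day along one meridian; it cannot
  resolve ambiguity in regions where the real SST field is zonally complex.
* The wintering-area bootstrap assumes enough pooled positions (≥30) per
  basin; a basin represented by a single short track yields direction-only
  records.
* Movement metrics inherit the once-daily sampling: sub-daily commuting is
  invisible, and travel speed is known to be biased low by boundary blur at
  the day scale even after edge screening.
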