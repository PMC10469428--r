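---
title: "From raw biotelemetry to behavioural inference: models and design choices"
author: "movestates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw biotelemetry to behavioural inference: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the pipeline answers

A defining trait of classical migration is that maintenance activities --
above all feeding -- are suppressed during directed long-distance movement.
For a diving predator such as the beluga whale this is testable with
satellite-tag data: decode each hour of a track as either area-restricted
search (ARS; slow, tortuous) or Transit (fast, directionally persistent),
isolate the long-distance movement phases between seasonal residency areas,
and ask what fraction of Transit hours contain foraging dives. If that
fraction is high, the animal forages while "migrating" and the movement does
not conform to the classical syndrome.

`movestates` implements the full chain from raw mixed Fastloc-GPS/Argos
location tables and dive-event tables to that statistic, plus a seeded
synthetic generator with the statistical structure every stage assumes, so
the whole pipeline is testable end to end without access-restricted tag
data.

## Stage 1: location quality control (`qc_track`)

Tag locations are heterogeneous: GPS fixes carry a satellite count and a
residual, Argos fixes carry an error ellipse. The filtering cascade is
rule-based and removal-only:

* GPS fixes with fewer than 5 satellites and/or residual above 35 are
  removed; survivors get a nominal 50 m circular error ellipse.
* Argos fixes with semi-major axis error above 3 km are removed.
* A speed-distance-angle filter removes Argos fixes whose implied speed
  from *both* neighbours exceeds 5 m/s (worst violator first, iterated),
  then spike geometries: inner angle below 15 (resp. 25) degrees with both
  adjacent segments at least 2500 (resp. 5000) m.
* Argos fixes strictly within 10 min of a GPS fix are removed (exactly
  10 min is kept); then any fix with error above 500 m within 20 min of a
  fix at or below 500 m.
* Tracks split at gaps strictly greater than 6 h; segments with fewer than
  4 locations or spanning less than 3 h are dropped.

All comparisons are strict exactly as stated; boundary values survive.
Distances and bearings are ellipsoidal (geosphere). Because every removal
can expose new violations among the surviving neighbours -- including rows
dropped with short segments -- the per-animal chain is swept to a fixed
point, which makes the whole cascade idempotent: re-running it on its own
output changes nothing. The sweep preserves the stated stage order; the
iteration count is almost always 1-2.

## Stage 2: continuous-time correlated random walk (`fit_ctcrw`)

Within each segment, position is modelled per axis as the integral of an
Ornstein-Uhlenbeck velocity process with autocorrelation decay `beta` (1/h)
and diffusion `sigma` (km h^-3/2); the two axes share the parameters
(isotropy -- standard practice, and it halves the parameter count) but are
coupled through each fix's full 2x2 error-ellipse covariance (axes treated
as 1-sigma). The exact Gaussian likelihood is evaluated with a Kalman
filter over the irregular fix times and maximised over `(log beta, log
sigma)` by BFGS (relative tolerance 1e-8, at most 500 iterations). The
filter prior is centred on the first observation with a 10 km position
standard deviation and zero velocity with a 5 km/h standard deviation: a
proper, weakly informative prior rather than an improper diffuse one, so
the likelihood is a well-defined joint Gaussian (which is also what the
test-suite oracle evaluates densely).

Numerical points worth knowing:

* For `beta * dt` below 1e-4 the closed-form process noise cancels
  catastrophically; a series expansion is used instead, and `(beta, sigma)`
  are clamped to `[1e-4, 1e3] x [1e-6, 1e4]`, far outside any plausible
  fit.
* A near-stationary track drives `sigma` to its lower boundary; the fit is
  flagged (`boundary = TRUE`) rather than failed.
* Hourly positions come from the fixed-interval (RTS) smoother evaluated on
  the union of fix times and every whole hour strictly inside the segment
  span -- no extrapolation, and in particular never across the greater than
  6 h gaps that segmentation was designed to avoid interpolating.
* Every consecutive pair of hourly predictions is speed-checked against
  5 m/s; offending predictions are flagged in the output, mirroring the
  visual plausibility check that modelled tracks should not demand
  unrealistic speeds.

Parameters are fitted per segment by default; `share_ctcrw = TRUE` pools
segments of one animal into a single fit, since neither choice is forced by
the data and segments of one animal are plausibly exchangeable.

## Stage 3: the two-state movement HMM (`fit_hmm`)

Hourly step lengths (gamma, parameterised by mean and standard deviation in
km, matching how such estimates are reported) and turning angles (von
Mises, mean fixed at 0 for both states, since only concentrations are
reported for this population) are emitted by a two-state Markov chain:
ARS and Transit. The likelihood is the product over all segments of all
animals, each segment starting from the initial distribution `delta`
(default: the stationary distribution of the transition matrix, recomputed
during optimisation; `delta = "uniform"` is available because the
convention is not universal). Steps below 1e-6 km are floored at 1e-6 km:
smoothed positions are continuous-valued, and the floor keeps gamma
densities with shape below 1 finite.

Fitting is multi-start, following a fixed protocol:

* `m1`: step means 1 and 5 km, sds 2 and 3 km, concentrations 1 and 13.
* `m2`: restart from the `m1` estimates (a convergence self-check).
* `m3`, `m4`: the `m1` estimates scaled by 0.75 and 1.25 (the protocol
  calls for starts below and above the first fit; the 25% factor is this
  package's choice).
* `m5`: a deliberately extreme start -- the minimum observed step length as
  the ARS mean and the maximum as the Transit mean.

Each fit is screened for degeneracy (any off-diagonal transition
probability below 1e-4, or any state step mean below 0.01 km -- the
signature of a biologically meaningless optimum, e.g. an "ARS" state that
only absorbs interpolation jitter), and converged non-degenerate fits are
compared at a relative tolerance of 1e-3 per parameter; disagreement raises
a *non-identical convergence* warning and is recorded per start in the
diagnostics table. The selected model is the best converged non-degenerate
fit, states relabelled so ARS always has the smaller step mean. On clean
synthetic data `m5` routinely converges to a degenerate optimum and is
rejected, which is exactly the behaviour the screen exists to catch.

Posterior state probabilities come from the forward-backward algorithm; an
hour is labelled ARS or Transit only when its larger posterior reaches 0.9,
otherwise `Uncertain`, which keeps its probabilities but is excluded from
all downstream summaries.

## Stage 4: seasonal utilization distributions and phase labels

Residency must be separated from long-distance movement before the
foraging question is asked. ARS-labelled hours from all animals are pooled
by season window -- April-September (summer, bandwidth 75 km) and
October-March (winter, bandwidth 100 km) -- into a Gaussian kernel density
on a shared 10 km projected grid (the bandwidth is the kernel standard
deviation). The 50% region is the smallest set of cells holding half the
mass; the contour level is placed strictly between the last included and
first excluded cell densities so no grid node sits exactly on the contour.
Membership is bilinear interpolation of the density at or above the level,
so points exactly on the contour count as inside. Fewer than 30 seasonal
ARS locations is an error: a kernel density on less support is not worth
drawing a contour from.

`extend_to_land()` implements the "extend to the nearest land barrier"
idea operationally: coastline rings are densified, every boundary cell of
the 50% mask is connected to its nearest coast point when that lies within
a configurable reach (default 100 km), the cells along those connecting
segments are added, and a light morphological closing removes slivers. If
no coast is within reach the region is unchanged, and extension can only
add area. This is a documented stand-in for an unspecified operational
rule; the reach is a parameter, and the output records whether extension
occurred.

Phase labelling partitions every decoded hour: inside either extended
region is `residency`; outside both, the hour belongs to `fall` if the
animal most recently departed summer residency (or has not yet been
resident anywhere) and `spring` if it most recently departed winter
residency. Two conventions matter here. First, points on a contour are
residency. Second, "departed" refers to sustained residency runs: each
maximal run of consecutive residency hours is attributed to the season
whose density, relative to its own contour level, dominates over the run.
The pooled seasonal kernels can overlap in space -- early-winter ARS hours
dated September fall inside the summer month window and put summer-UD mass
over the winter area -- and an instantaneous polygon-identity rule would
let a few hours of flicker into that overlap relabel an entire subsequent
leg.

## Stage 5: dive linkage (`summarize_foraging`)

Four dive-profile classes count as foraging: Deep Benthic, Deep Pelagic V,
Deep Pelagic W, and Intermediate Benthic; the skew-shaped drift class is
excluded, and unknown labels are excluded with a warning. A dive belongs to
the hour containing its start time (half-open bins `[t, t+1h)` aligned to
the hourly locations; a dive at exactly 11:00:00 is hour 11). An hour is
complete only if its depth record exists and no dive starting in it crosses
into an hour with missing depth data -- a crossing dive cannot be
characterised, so the hour it started in is unusable; this rule needs dive
durations, which is why the dive-event schema carries `duration_s`.

Summaries are formed after excluding Uncertain hours, residency hours and
incomplete hours (three commuting filters): per state and leg, the
percentage of hours with at least 1 and at least 2 foraging dives plus the
full count histogram, and -- from all long-distance decoded hours -- the
percentage of time in Transit, per animal (mean and range) and pooled.
Pooled and per-animal-mean percentages are both reported because either
convention is defensible and they differ when animals contribute unequal
hours. A state-leg cell with no hours is reported as empty, never as 0%.

## The synthetic generator: what it emulates and what it does not

`sim_config()` defaults describe six tagged animals: a summer residency, a
meandering fall movement to a winter area about 1400 km away, a duty-cycled
winter residency, and a spring return. The emission structure is exactly
what the HMM assumes -- gamma steps, von Mises turns, Markov switching --
with state parameters defaulting to the fitted values for this population
(step means 2.09/4.39 km, sds 1.37/1.15 km, concentrations 1.22/10.97).
Two transition matrices are used because observed Transit occupancy differs
sharply between movement (~75%) and residency (~39%); a single chain cannot
produce both. During movement phases a small heading correction
(`nav_gain = 0.08`) pulls Transit headings toward the destination, giving
realistically meandering rather than beeline tracks (fall legs cover
roughly 2-3 times the straight-line distance); movement phases end on
arrival, so durations vary between animals. Observations are linearly
interpolated off the true hourly path and corrupted: GPS at 7-30 min
intervals (25 m error; 5% of fixes carry failing quality fields and
inflated error), Argos with log-normal error ellipses, 2% gross outliers
displaced 5-50 km with inflated ellipses, scheduled gaps of 8-36 h, and a
winter programme with GPS on every 7th day only. Dive counts are Poisson
per hour with state-dependent rates (ARS 2.5/h, Transit 1.8/h totals across
the four foraging types -- free parameters, since per-state rates are not
published for this population), and depth-record missingness arrives in
runs with a long-run rate of 0.6.

Deliberate simplifications, which bound what passing tests can show about
real data:

* The timeline is compressed (winter residency ~58 days rather than ~5
  months) to keep full runs at desk scale; one visible consequence, overlap
  between the pooled seasonal kernels, is handled by the run-majority
  departure rule described above.
* Measurement errors are independent Gaussian draws; real Argos errors are
  heavy-tailed and temporally correlated, and no Argos location-class
  structure is simulated.
* The coastline shipped for examples (`synthetic_coastline()`) is a
  synthetic undulating shoreline, not real geography, and the true paths
  ignore land entirely.
* Dive types are sampled labels; the time-depth classifier that produces
  them in reality is out of scope, as is any 75 s depth series.
* Tags never fail mid-deployment; every animal completes the full cycle.

## Problem sizes and experiment design

The recovery experiment behind the acceptance surface simulates ~15,000
hourly steps (30 segments of 500 across 6 animal ids, matching the order of
magnitude of the real decoded data set) at the published estimates, refits
from the `m1` start, and takes the median over 20 replicate seeds; median
recovered parameters land within a few percent of truth. The CTCRW checks
compare the Kalman likelihood to a dense joint-Gaussian evaluation on
segments of up to 8 fixes (tolerance 1e-6) and recover `(beta, sigma)`
from 50 replicates of 500-fix tracks. The forward recursion is checked
against brute-force path enumeration on 200 random short series (tolerance
1e-10). The end-to-end closure run uses the generator defaults (six
animals, ~20,000 truth hours) and verifies that the pipeline's
Transit-hour foraging proportion lands within 3 percentage points of the
generator's own truth and that phase labels agree with truth at 90% or
better.

## Known limitations

* The land-extension rule is an operational stand-in; different reasonable
  rules would move a small number of near-shore hours between residency and
  long-distance.
* Fall/spring attribution depends on the seasonal kernels; with very sparse
  winter data an animal whose winter residency is never decoded would have
  its spring leg labelled fall (a warning is raised when an animal never
  enters any polygon).
* CTCRW smoothing shrinks step lengths and straightens turns slightly, so
  HMM parameters refitted on smoothed synthetic tracks sit a few percent
  from the generating values even when the HMM itself is exact; the
  acceptance experiment therefore measures recovery on directly simulated
  series, where the model is correctly specified.
* Percentages pooled across animals weight animals by their data volume;
  the per-animal means are reported alongside for the opposite convention.
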