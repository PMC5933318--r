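---
title: "Switching state-space models for Argos whale tracks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching state-space models for Argos whale tracks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dcrws` implements the analysis chain used to study the movements of
satellite-tagged blue whales migrating between a mid-latitude feeding ground
(Chilean Northern Patagonia) and tropical waters near the Galapagos: cleaning
and segmenting raw Argos locations, a hierarchical Bayesian two-state
switching first-difference correlated random walk (DCRWS) state-space model
fitted by MCMC, classification of behavioral modes into transit and
area-restricted search (ARS), movement descriptors, and dive statistics from
archival-tag depth series. A synthetic-data generator with full ground truth
makes every stage testable without any telemetry deposition.

## The model

### Process model

Let $x_t$ be the true (unobserved) location, in longitude/latitude degrees,
at regular grid time $t$ (grid step 48 h for the broad-scale model, 6 h for
the fine-scale model), and $d_t = x_t - x_{t-1}$ the displacement. Movement
follows a first-difference correlated random walk whose parameters switch
between two discrete behavioral states $b_t \in \{1, 2\}$:

$$d_t = \gamma_{b_t}\, R(\theta_{b_t})\, d_{t-1} + \varepsilon_t,
  \qquad \varepsilon_t \sim N_2(0, \Sigma),$$

where $R(\theta)$ is the rotation by the mean turning angle $\theta$ and
$\gamma \in [0,1]$ is the move persistence (autocorrelation in speed and
direction). State 1 is transit — strongly persistent, low-turn movement,
migratory in this system; state 2 is ARS — weakly persistent movement with
high turning, associated with foraging. Identifiability is enforced by the
ordering $\gamma_1 > \gamma_2$ at every MCMC draw, which also pins the state
labels across chains. States follow a Markov chain with switching
probabilities $\alpha_k = P(b_t = 1 \mid b_{t-1} = k)$.

### Observation model

Argos fixes arrive irregularly and with class-dependent, heavy-tailed error.
Each fix is assigned to the grid interval containing it, with fractional
position $j \in [0, 1)$ (half-open intervals: a fix exactly on a grid time
starts that interval; only a fix at the final grid time carries $j = 1$). The
fix is predicted by linear interpolation, $(1-j)\,x_i + j\,x_{i+1}$, and each
coordinate residual follows a scaled Student-t whose degrees of freedom
$\nu$ and scale $\tau$ (degrees) depend on the Argos location class
(3, 2, 1, 0, A, B). Intervals without fixes contribute process terms only.

The class error table is *fixed*, not estimated — six classes times two
coordinates would be poorly identified from a handful of tracks. The shipped
defaults (see `argos_tdist()`) are calibrated to the widely reported Argos
error magnitudes — scales from 0.003° (class 3, a few hundred metres) to
0.045° (class B, several km) with degrees of freedom falling from 6 to 1.2 so
the poor classes are strongly heavy-tailed — and the table is a plain
argument: supply your own fits when your tag programme has them.

### Hierarchy, priors, MCMC

Movement parameters ($\gamma$, $\theta$, $\alpha$, $\Sigma$) are shared
across individuals; latent paths and state sequences are per track. Joint
estimation pools the little information each error-prone track carries about
the shared dynamics, which is what makes per-individual state estimation
workable.

Priors (all configurable through `dcrws_priors()` and the parameter
constructors): $\gamma_k \sim \mathrm{Beta}(1,1)$, $\alpha_k \sim
\mathrm{Beta}(1,1)$, $\theta_k$ uniform on $(-\pi, \pi]$ (a Beta(1,1)
variable rescaled to the circle), half-t(3, scale 1°) on the process-noise
SDs and uniform on the correlation. These are deliberately flat: the desk
experiments in this package give the likelihood every opportunity to speak.

The sampler (Rcpp) is Metropolis-within-Gibbs:

* **states**: forward-filtering backward-sampling (FFBS) — an exact joint
  draw of $b_{1..T}$ given path and parameters, with the process densities as
  emissions. We first tried single-site Gibbs; it mixes too slowly at desk
  scale (occasional $\hat R > 1.1$ at $2 \times 15{,}000$ iterations) and its
  sticky, spuriously flipping state paths bias the switching probabilities
  upward. FFBS costs $O(T)$ per sweep and removed both problems.
* **locations**: per-site bivariate random-walk Metropolis with per-site
  proposal scales adapted during burn-in only (Robbins–Monro toward 0.3
  acceptance), plus a 5% mixture of fixed process-scale (0.05°) "kick"
  proposals so a site whose scale has shrunk to a precise fix's scale can
  still escape a biased initialization.
* **parameters**: random-walk Metropolis on $\gamma_k$ (rejecting draws
  violating the ordering), wrapped random walks on $\theta_k$, log/atanh
  random walks on the SDs and correlation, and conjugate
  $\mathrm{Beta}(1 + n_{k\to1},\, 1 + n_{k\to2})$ Gibbs draws for
  $\alpha_k$. Parameter sweeps run three times per location sweep — they are
  cheap relative to the path update and mix slowly otherwise.

Chains start over-dispersed (distinct $\gamma$, $\theta$, $\alpha$, $\Sigma$
starting points per chain; latent paths initialized by linear interpolation
of the fixes plus chain-scaled jitter, capped at 20 median observation scales
so precise data cannot strand a chain thousands of SDs from the posterior).
Chain $c$ uses sub-seed `seed + c`; every result is reproducible from one
integer.

The reference estimation protocol is 2 chains × 120,000 iterations, 100,000
burn-in, thinning by 20 — 2,000 retained samples. `mcmc_config()` enforces
the bookkeeping exactly (thinning must divide the post-burn-in length;
at least 100 retained draws per chain). Convergence is assessed by the
Brooks–Gelman–Rubin potential scale reduction factor (`gelman_rubin()`);
any $\hat R > 1.1$ flags the fit non-converged — a warning, never a
discarded result.

### Behavioral modes and descriptors

The continuous behavioral mode at a grid point is the posterior mean of the
sampled discrete state over retained draws, $m \in [1, 2]$ (grid point 0
inherits the first step's state). Classification is conservative: $m \le
1.25$ transit, $m \ge 1.75$ ARS, in between unclassified; threshold values
take the classified label, since the buffer is already built into the
thresholds. Movement descriptors are computed from the posterior mean path:
total great-circle distance (haversine, radius 6,371 km), distance per day
(inclusive calendar-day duration — the convention that reproduces the
published deployment table, where a 2013-04-01 to 2013-05-15 track lasts 45
days), and per-state step speeds (displacement over step duration; sample SD;
min–max range; `na` when a state never occurs). Each step takes the label of
its ending grid point. Whether published per-state SDs were taken over steps
or over posterior draws is not stated anywhere we know; per-step is
implemented.

## Track preparation

* **Speed filter**: iterative removal of fixes whose implied great-circle
  speed to both temporal neighbours exceeds a threshold; endpoints are judged
  by their sole neighbour and only removed when no interior fix is flagged
  (one neighbour is weaker evidence). Default 30 km/h — about three times the
  fastest published transit speed (10.2 km/h) — so only clear artefacts go.
  The filter is idempotent, reports the removed fraction, and warns (never
  fails) past a configurable removal budget (default 4%).
* **Gap splitting**: tracks are cut at transmission gaps longer than 28 days
  (about the month-long gap that split one published track into two), with
  alphabetic segment suffixes. During fitting, runs of more than 10 fix-less
  grid steps split a track rather than bridging the void with pure process
  prediction.
* **Duplicates** (same tag and timestamp): the better location class wins;
  ties keep the first row. Longitudes are normalised to $[-180, 180)$.

## Dive analysis

Archival depth bouts (1–4 h continuous recordings at 75 s resolution) are
validated for exact sample spacing; a missing sample splits the bout. A true
dive is a maximal run of samples strictly exceeding 10 m (about half a body
length), separating dives from surface respiration; the shortest reportable
dive is one sample (75 s). Three statistics per dive: maximum depth, duration
(run length × resolution), and post-dive interval (surface time to the next
dive in the same bout; undefined for a bout's last dive). Dives never span
bouts, and dive + surface time partitions each bout exactly — a conservation
law the tests enforce.

Each dive is tagged day or night by the sign of the solar elevation
(standard low-precision NOAA solar geometry; geometric horizon, no twilight
allowance) at its *start* time, at the position interpolated from the fitted
track — the start is the single unambiguous timestamp a dive owns. Statistics
are aggregated two ways: per state-space grid bin and diel class (mean,
sample SD, range; empty bins omitted; one-dive bins report SD 0), and per tag
and diel class for whole-deployment summaries.

## The synthetic generator

`sim_scenario()` / `simulate_track()` forward-simulate the exact model the
fitter assumes: a two-state switching DCRW in lon/lat degrees (the fitting
space — deliberately, so recovery tests are exact), observed through
duty-cycled Argos fixes. Fix times follow a Poisson process within
transmitting days (daily or alternate-day duty cycles, emulating tags that
transmitted every other day after May); classes are drawn from a configurable
mix; t-distributed error is added per class and coordinate. By default a
class-3 fix anchors the exact start and end times so the fitted grid
coincides with the simulation grid and states align one-to-one.
`simulate_dives()` lays 1–4 h bouts of flat-bottomed dives whose depth and
duration distributions switch between day and night regimes by solar
elevation along the simulated path, with every generated dive's truth
returned.

Defaults emulate an austral-autumn deployment off Chiloé: start at
(−73.5, −42), 6 h steps, $\gamma = (0.85, 0.15)$, dwell 10 steps, process
noise 0.08°/step (transit speeds of a few km/h), ~8 fixes per transmitting
day, and the realistic Argos class mix dominated by the poor classes
(A + B = 55%). Dive regimes default to deep/long by day (mean 150 m, 450 s)
and shallow/short by night (25 m, 225 s), the diel pattern seen in
krill-tracking whales.

**What the generator does not emulate**: real tracks have
environment-driven, non-stationary movement, location error that need not be
exactly t-distributed per class, tags whose error scales drift, and dives
with structured shapes (V/U) rather than flat bottoms. Passing recovery
tests therefore demonstrate the estimator is correct *under its own model
assumptions* — they cannot certify behavior on real ocean data.

### The recovery scenario, and an identifiability caveat

`sim_scenario_recovery()` is the named fixture behind the package's core
validation: 200 six-hour steps, $\gamma = (0.85, 0.15)$, $\theta = (0, \pi)$
(course-reversing ARS — the classic high-turn signature), $\alpha = (0.9,
0.1)$, and a *moderate*-noise class mix (A + B = 20%). Under these
conditions, 95% credible intervals cover the generating $\gamma_1, \gamma_2,
\alpha_1, \alpha_2$ at roughly their nominal rate (≈90–95% per parameter
over 20-replicate batches; at $n = 20$ a binomial draw around those rates is
expected), and ~93% of classified steps receive the correct label with
roughly 70–75% of steps classified at the conservative 1.25/1.75
thresholds.

The caveat found while designing that fixture: under the *deployment
realistic* heavy class mix (55% A/B with strongly heavy tails) at a 6 h
grid, the two states are **not** reliably identifiable from a single
200-step track — posterior modes hover in the unclassified band and the
switching probabilities drift toward their priors. That is a property of the
data regime, not of the sampler (it persists with exact observations only
when the turn-angle contrast is also removed, and disappears under the
moderate mix). It is one reason the original analysis pooled individuals and
used a 48 h grid, where per-step displacements dwarf Argos error.

## Numerical choices and degenerate inputs

* Grid: $T = \lceil \mathrm{span}/\mathrm{step} \rceil$ steps from the first
  fix; a track spanning less than two steps is an error.
* `dcrws_params()` allows $\gamma_1 = \gamma_2$ and zero process noise so
  degenerate simulations (straight-line paths) are expressible; *estimation*
  always enforces the strict ordering.
* Exactly-boundary behavioral modes (1.25 / 1.75) take the classified label;
  modes outside $[1, 2]$ are a domain error.
* An empty depth bout, a bout never exceeding the threshold, and a track
  state with zero steps all produce well-defined empty/`na` results, not
  errors.
* All timestamps are UTC throughout; day counting uses UTC calendar dates.
* Problem sizes for the shipped validation runs (chosen to keep a full
  validation batch in minutes on a laptop core): 20 replicates × 200 steps at
  2 chains × 15,000 iterations (7,500 burn-in, thin 5) for recovery; 60-step
  tracks with near-zero observation error and 24 fixes/day for the
  noiseless-limit distance check, which lands well inside 1% of the true path
  length.

## Limitations

* Two states only, discrete time, no environmental covariates on switching,
  no continuous-time formulation.
* The model works in raw lon/lat degrees, as the original DCRWS formulation
  does, so process noise is anisotropic in kilometres away from the equator;
  descriptors are computed great-circle downstream, but the latent dynamics
  inherit the distortion. At the latitudes spanned here (0–45°S) this is
  modest; near the poles it would not be.
* Fixed, literature-calibrated observation error table; misspecified class
  errors propagate into the paths.
* The published per-whale dive summaries cannot be recomputed (the archival
  depth data were never deposited); the dive module is validated entirely
  against generator ground truth.
* Real-data reproduction of published track distances requires the raw Argos
  deposition, which must be supplied by the user as
  `inst/extdata/argos_raw_locations.csv`; the full-dataset pooled speed and
  daily-distance figures additionally need multi-month batch fits that are
  beyond desk scale.
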