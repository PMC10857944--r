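---
title: "Methods: contacts, land-cover models and spatiotemporal interval tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contacts, land-cover models and spatiotemporal interval tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

camtrapTI analyses multi-station, multi-species camera-trap surveys. This
vignette documents the statistical procedures, the assumptions they make,
the tunable parameters, the numerical conventions, and what the simulation
evidence in the test suite does and does not establish.

## Data model

A survey is two tables. The *deployment* table has one row per camera
station: an active interval `[start, end)` and one of six land-cover
classes (clearfell, coniferous plantation, grassland, heathland and
shrubland, wetland, woodland). The *detection* table has one time-stamped
species record per image. Timestamps are timezone-naive local civil time;
the analysis only ever uses time differences and time of day within a
single site and season, so no DST arithmetic is attempted. The deployment
interval is closed-open: a detection stamped exactly at `end` is rejected,
which keeps effort accounting unambiguous. Detections outside their
station's window are collected into a rejects report rather than silently
dropped. Each station has exactly one deployment row; duplicated stations
are a hard error, matching the single-placement survey design the package
targets.

## Independence filtering

Camera traps photograph the same animal repeatedly while it stands in
view. The standard remedy is to keep only independent *contacts*: within
each (station, species) stream the first detection opens a contact, and a
later detection opens a new one only when separated by more than
`window_minutes` (default 30, the conventional choice in the camera-trap
literature).

"Separated" admits two readings and the package implements both:

* **rolling** (default): the gap is measured from the immediately
  preceding detection. A sequence stays unbroken while consecutive gaps
  remain at or below the window, even if it spans hours in total. This is
  the sequence reading: a burst of images with no 30-minute silence is one
  visit.
* **from_contact**: the gap is measured from the contact's opening
  detection, so a long unbroken sequence is still chopped every window.

Field studies rarely state which variant they used; the default follows
the sequence reading and `independence_mode` exposes the other for
sensitivity analysis. Two further conventions: a gap of exactly the window
merges ("greater than" is read strictly), and `window_minutes = 0` returns
every detection, which is the identity limit used in tests. The filter
cannot distinguish individuals; a herd that keeps a camera busy for an
afternoon is one contact, which is a known, accepted bias of the method.

## Detection-rate models

For one species, per-station contact counts $y_i$ are modelled as

$$y_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\log \mu_i = \beta_0 + \beta_{\mathrm{lc}(i)} + \beta_h h_i + \log d_i,$$

with $h_i$ the station's human detection rate (human contacts per
trap-day), $d_i$ the deployment duration in days entering as an offset,
and clearfell the reference land cover. Fitting is by maximum likelihood
(`MASS::glm.nb`), with `theta` estimated jointly; convergence uses a
relative deviance tolerance of `1e-8` and up to 100 iterations. The model
assumes counts are independent across stations given land cover and human
rate — no spatial autocorrelation, no station random effects.

*Overdispersion.* The Pearson dispersion ratio (sum of squared Pearson
residuals over residual degrees of freedom) of the Poisson fit of the same
formula motivates the negative binomial; the verdict threshold defaults to
1.4, a common working rule, and is configurable.

*Pseudo-R².* Reported as Nagelkerke (Cragg–Uhler), computed against the
intercept-plus-offset null; the metric name is printed wherever the value
appears, since "R²" alone is ambiguous for count GLMs.

*Separation.* A land-cover level with zero contacts drives its coefficient
toward $-\infty$ with an enormous Wald SE. The package flags any
coefficient whose SE exceeds 10 on the log scale (configurable) and
propagates the flag to every contrast involving that level, rather than
switching to a penalized fit: surfacing the degenerate cell is more honest
than hiding it, and small surveys produce such cells routinely. For the
same reason confidence intervals are Wald rather than profile-likelihood.
Terms with no variation across stations (a single observed land-cover
level, or an all-constant human rate) are dropped automatically, which
covers intercept-only designs where the MLE reduces to the closed-form
rate `total contacts / total trap-days`.

*Estimated marginal means.* The EMM of level $l$ is the linear predictor
at $l$ with the human rate fixed at its across-station arithmetic mean
(the standard least-squares-means convention) and the offset set to
$\log(1)$ day, so `exp(EMM)` is predicted contacts per day. Because every
EMM conditions on the same covariate value, pairwise contrasts reduce
exactly to differences of land-cover coefficients, with SEs from the
coefficient covariance. The 15 pairwise p-values are unadjusted by
default — many field analyses report them raw — with a Tukey
(studentized-range) adjustment available via `adjust = "tukey"`. The
implementation is plain linear algebra on the fit and is cross-checked
against the emmeans package in the test suite.

## The spatiotemporal interval test

The core inferential tool asks, for a directed pair, whether the follower
species arrives sooner after the leader than chance predicts.

*Statistic.* At each station, every follower contact preceded by at least
one leader contact contributes the time since the **most recent preceding**
leader contact; intervals are pooled across stations and their median
taken (mean-of-central-pair for even counts). Pooling across stations
before taking the median treats the survey as one experiment; a
per-station-median alternative would weight sparse stations equally with
busy ones. All qualifying follower contacts contribute, not just the first
after each leader; `pairing_mode = "first_after_leader"` exposes the
stricter variant. Intervals are not capped by default (`max_lag_hours`
allows sensitivity analysis), and a follower contact with no preceding
leader at its station contributes nothing.

*Null.* Each replicate re-timestamps every follower contact: the station
is kept, the date is drawn uniformly from that station's active calendar
dates, and the time of day is drawn from the follower's *diel activity
pattern* — by default the empirical multiset of the follower's observed
clock times pooled across stations, resampled with replacement. The
empirical distribution is assumption-free; a circular KDE variant
(von Mises kernel, concentration `kappa`, default 50 ≈ a 20-minute kernel
SD) is available but not the default. A draw landing outside the
deployment window (possible on partial first/last days) is rejected and
redrawn, keeping null events inside effort windows. Leader contacts and
all other species are untouched, and per-station follower counts are
conserved, so the null destroys exactly one thing: the temporal linkage
between the pair. Randomized follower events are deliberately **not**
re-passed through the independence filter — refiltering would change
per-station counts and break that conservation.

*Inference.* With $Q$ the proportion of the 1000 null medians greater than
the observed median (a null median exactly equal to the observed one
counts one half — an unbiased two-sided treatment of ties, which are
possible at minute resolution), the two-sided p-value is
$p = \min(Q, 1-Q) \times 2$, capped at 1. A $p$ of exactly 0 is printed as
`< 1/reps` since the resolution of a randomization test is bounded by its
replicate count. The percent difference
$100(\tilde m_{\mathrm{null}} - \tilde m_{\mathrm{obs}})/\tilde m_{\mathrm{null}}$
is positive when the observed median is shorter than expected — the
attraction direction — and the 2.5th/97.5th null percentiles give a 95%
band. Replicates yielding no interval are excluded from $Q$ and counted;
more than 20% invalid replicates flags the result unreliable. Pairs with
no observed interval are returned untestable with an explanatory reason
rather than erroring. No multiplicity correction is applied across the 12
directed pairs; the output says so.

*Reproducibility.* One master seed drives everything. Each (pair,
replicate) uses a deterministically derived substream, so a pair's result
is identical whether run alone or inside `run_all_pairs()`, in any order.

## The synthetic survey generator

The generator exists so that every stage can be validated without field
data, and its defaults describe the survey regime the package targets: 39
stations split 2/8/8/6/5/10 across the six land covers, 28-day deployments
staggered over 5 start days, four ungulates with station-weighted mean
detection rates of 0.60, 0.12, 0.04 and 0.11 contacts per day, and humans
at 0.30 contacts per day. Per station and species, a total event count is
drawn from a negative binomial with mean
`duration * exp(base + landcover offset)`; the dispersion parameters
(sika 0.45, roe 0.65, red 0.75, boar 0.35) were back-calculated once from
the targeted mean/SD regime of per-station rates and left alone. Event
times are placed independently given the count — uniform active date plus
a diel draw, rejection-sampled into the window — which matches the
count-model assumptions of the GLM stage rather than simulating a
sequential hazard. Diel profiles are mixtures of one or two wrapped von
Mises bumps (crepuscular deer: peaks near 05:30 and 20:00; nocturnal boar:
peak near 01:00; diurnal humans: peak 13:00), sampled with the vectorized
Best–Fisher algorithm; wrapping handles midnight correctly where a
truncated normal would not.

Attraction is injected by converting each follower event, independently
with probability `pi` (preset 0.4) and only at stations where the leader
occurs, into a timestamp equal to a uniformly chosen leader event plus an
exponential lag (preset mean 2 h), redrawn until inside the window.
Conversion replaces timestamps in place, so per-station counts are
conserved — the same invariant the test's null relies on. An optional
burst expander (on by default) turns each contact-level event into 1–5
images within 2 minutes so the independence filter has realistic input.

What the generator does *not* emulate: spatial autocorrelation between
stations, animal movement and home ranges, seasonal trends, group-size
variation, imperfect and species-specific detectability, camera failures.
Passing tests therefore show the pipeline is correct and well-calibrated
*under its own assumptions*; they cannot show the assumptions hold for any
particular field dataset.

## Validation problem sizes

The test suite validates operating characteristics by simulation at these
sizes, chosen to bound Monte-Carlo error while keeping the default test
run comfortably interactive: type-I error of the interval test on 300
attraction-free surveys at the 39-station scale (200 null replicates per
test, nominal band 0.02–0.08 at α = 0.05); power on 100 attraction-injected
surveys at the same scale (expected ≥ 80%); 95% Wald CI coverage of known
land-cover effects over 200 surveys of 200 stations (accepted band
0.91–0.99, the GLM-stage checks using raw event counts so that filter
merging does not bias the count model being tested); and exact equivalence
of the independence filter and interval pairing against independent
brute-force oracles on hundreds of random streams of up to 30 events.
`scripts/acceptance.R` recomputes the same quantities (type-I at 150
surveys) from the installed package.

## Known limitations

* Naive occupancy and detection rates carry no detectability correction;
  they are comparable within a consistent survey design, not across
  designs.
* The NB GLM treats stations as independent; surveys with strong spatial
  structure need a different model class.
* Wald inference under separation is flagged, not fixed; users with
  degenerate cells who need estimates should refit with a penalty or an
  informative prior outside this package.
* The interval test conditions on the follower's *observed* diel pattern,
  estimated from the same data being tested; with very few follower
  contacts the null becomes noisy, which the invalid-replicate and
  untestable flags surface but cannot cure.
* The p-value resolution is `1/reps`; findings at the margin of
  significance deserve a larger `reps`.
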