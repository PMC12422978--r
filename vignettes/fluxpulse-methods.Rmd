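---
title: "Rain-pulse detection and bias correction: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rain-pulse detection and bias correction: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, what the synthetic
generator emulates, the numerical choices, and the known limitations.

## The phenomenon and the bias

Rewetting dry soil triggers a burst of heterotrophic respiration (the
Birch effect) that decays over the following days. In eddy-covariance
records the pulse is visible directly in net ecosystem exchange (NEE,
positive = flux to the atmosphere), because microbes respond to rain much
faster than vegetation. The night-time partitioning method, however,
derives ecosystem respiration from a temperature-response model

$$R_{\mathrm{eco}}(j) = R_{\mathrm{ref}}\,\exp\!\left[E_0\left(
\frac{1}{T_{\mathrm{ref}}-T_0} - \frac{1}{T_{\mathrm{air},j}-T_0}\right)\right],
\qquad T_{\mathrm{ref}} = 288.15\,\mathrm{K},\; T_0 = 227.13\,\mathrm{K},$$

with $R_{\mathrm{ref}}$ estimated in short moving windows of night-time
data. Three things make this model nearly blind to pulses: rain usually
arrives with a cold front (the model then predicts *lower* respiration
exactly when the true flux spikes); post-rain nights are calm and humid,
so the turbulence screen removes most of their half hours and the moving
windows bridge the event at the pre-event level; and whatever elevated
night flux does survive is smeared over a multi-day window. The result is
a systematic underestimate of respiration — and of GPP, which is derived
as $R_{\mathrm{eco}} - \mathrm{NEE}$ — during and just before events.

## The correction

Pulse decay is described by first-order kinetics. At the site level,
$\mathrm{NEE}_{i} = \alpha_s e^{-k_s i}$ is fitted by nonlinear least
squares to the maxima, over all of a site's events, of the daily mean NEE
at each day index $i$ (day 1 = rain day). A site fit is called
significant when the Wald p-value of $k_s$ is below 0.05. Normalizing
each site's series by $\hat\alpha_s$ and pooling yields the cross-site
("universal") decay curve.

Per event, the decay rate $k$ entering the correction comes from a fit to
the per-day 68th percentiles of half-hourly NEE (the 68th percentile
tracks values one standard deviation above the centre of the daily
distribution while resisting outliers); if that fit is not significant at
$p < 0.1$, the same curve is fitted to the site-pooled per-day means of
half-hourly NEE across events. If both fail, the event is left
uncorrected.

The correction factor for event day $i$ is

$$\beta_i = \frac{\mathrm{NEE}^{98}_{1}}{R^{98}_{\mathrm{NT},1}}
\, e^{-k (i-1)},$$

where the numerator and denominator are the 98th percentiles of
half-hourly NEE and of night-time-method respiration over all valid half
hours of day 1 (day and night pooled; percentiles are type-7 throughout
the package). Corrected respiration is $\beta_i$ times the
night-time-method value at every half hour of day $i$, so at the day-1
half hour where the baseline reaches its own 98th percentile the
corrected value equals the observed 98th-percentile NEE. GPP is then
re-derived from the partitioning identity. Two deliberate consequences:

- Anchoring respiration to NEE assumes day-1 GPP is negligible after the
  antecedent dry spell. Where day-1 GPP is actually positive the true
  respiration is even larger, so the correction is conservative.
- $\beta$ has no floor except $R_{\mathrm{eco}} \ge 0$. Late in a long
  event $\beta_i$ can fall below 1 and pull corrected respiration under
  the baseline; the exponential decays to zero while real fluxes decay to
  a nonzero baseline, so the tail of long events is mildly
  under-corrected. This is the method's main structural limitation and it
  is visible in the synthetic validation (event-window respiration is
  recovered to roughly 90–95%, not 100%).

Because the 4-day $R_{\mathrm{ref}}$ window also leaks the pulse into the
days *before* an event, the prepulse period (as many days before the
start as the event is long, skipped if it overlaps an earlier event) is
refitted with 2-day windows.

## Tunable parameters

All knobs live in `fp_config()`; the most consequential are:

| parameter | default | meaning |
|---|---|---|
| `sw_night` | 20 W m⁻² | radiation threshold defining night |
| `sw_daytime` | 50 W m⁻² | daytime threshold for the EF mean |
| `qc_max` | 0 | largest QC flag counted as an original measurement |
| `min_valid` | 10 half hours | daily NEE aggregates below this go missing |
| `e0_window`, `e0_step` | 15, 5 d | sliding windows for the $E_0$ fit |
| `rref_window`, `rref_step` | 4, 2 d | moving windows for $R_{\mathrm{ref}}$ |
| `rref_min_obs` | 10 | night half hours a window needs to be used |
| `prepulse_rref_window` | 2 d | window for the prepulse refit |
| `k_p_sig` | 0.1 | acceptance p-value for the per-event $k$ fit |
| `p98_min_halfhours` | 10 | valid day-1 half hours required to anchor |
| `end_tol` | 0.25 | relative night-NEE tolerance ending a screened event |
| `max_length` | 26 d | event-length cap |

The antecedent-EF window is 15 days (14 is the other conventional
choice; both are presets of `prepulse_mean()`). The rule screen's jump
thresholds (`nee_jump` = 1 µmol m⁻² s⁻¹, `ef_jump` = 0.08) were
calibrated once against the synthetic generator, since the manual
criteria they mirror are qualitative. A window-based
$R_{\mathrm{ref}}$ estimate from fewer than ~10 night half hours is not
statistically meaningful, hence `rref_min_obs = 10`; windows that fail it
are skipped and the interpolation bridges them.

Night definition, the $E_0$ acceptance rule (relative standard error
below 50%, inverse-variance weighted mean over windows, bounds
[30, 450] K) and the 80/20 detector split are conventions, exposed as
configuration rather than asserted as facts about any particular
processing chain. Friction-velocity filtering is *not* re-implemented:
inputs are assumed already u*-screened, as in standard ONEFlux products.

## The synthetic generator

`generate_site()` builds half-hourly records in which every quantity the
pipeline estimates is known exactly. It emulates, deliberately:

- diel and seasonal NEE from a rectangular-hyperbola light response minus
  Lloyd–Taylor respiration with a seasonal $R_{\mathrm{ref}}$;
- sporadic rain (Bernoulli days, exponential depths) that raises the
  daily evaporative fraction stepwise, with exponential dry-down between
  events, and arrives with a cold drop in air temperature that relaxes
  over a couple of days;
- additive respiration pulses $\alpha\,e^{-k(\mathrm{day}-1)}$ (daily
  amplitude, diurnally modulated by the temperature factor so night NEE
  during events tracks true respiration), triggered only on sufficiently
  wet rain days over sufficiently dry soil, never overlapping, lengths
  within the observed 2–26-day range;
- gradual vegetation green-up: the water-availability factor driving GPP
  is the EF state smoothed with a ~5-day response time, so the microbial
  pulse is immediate but the GPP response lags — peak GPP is kept at a
  dryland-realistic ~4 µmol m⁻² s⁻¹ (short, sparse vegetation);
- ONEFlux-like QC provenance: a large share of night half hours flagged
  as gap-filled (heavier while the soil is wet, emulating the turbulence
  screen's wholesale rejection of calm post-rain nights, and on rain days
  for sensor degradation), with flagged values replaced by model-based
  fills the way gap-filled products do.

The last point matters most: without it the moving-window baseline simply
fits the elevated night NEE and there is no partitioning bias to correct.
The generator therefore reproduces the *regime* the correction addresses
— a baseline that misses pulses — rather than an idealized tower with
perfect data. What the generator does **not** emulate: real turbulence
statistics or u* thresholds, storage and advection errors, heteroscedastic
and non-Gaussian flux noise, energy-balance closure gaps, instrument
drift, and short-lived abiotic CO₂ displacement at the rain front.
Passing the synthetic suites therefore demonstrates internal consistency
and correct behaviour under the stated regime, not performance bounds on
any particular real site.

Problem sizes used by the test and acceptance runs — two-year single
sites for pipeline checks, five-site two-year panels for bias/contribution
statistics, six-to-eight-site five-year panels for the detector — were
chosen as the smallest sizes at which the statistics of interest stabilize.

## Numerical and design choices

- Nonlinear fits use Levenberg–Marquardt least squares with log-linear
  starting values; parameter significance is the Wald test from the
  least-squares covariance. Exactly fitting windows get a tiny
  standard-error floor so inverse-variance weights stay finite.
- Percentiles are type-7 (linear interpolation) everywhere.
- Day indexing: day 1 is the rain day. The site/event decay fits use
  $e^{-k i}$; the correction factor uses $e^{-k(i-1)}$. The two
  conventions are kept exactly as defined, and only the rate $k$ is
  shared between them.
- Night validation aggregates to daily night means before forming
  per-event percent bias. Valid night coverage during events is extremely
  uneven (a few half hours on wet nights, many once the soil dries), so
  raw half-hourly sums would weight the event tail by data density rather
  than by flux.
- Detection scoring matches true and predicted start dates within ±2 days
  by a truth-ordered earliest-available-prediction rule; with equal-width
  tolerance windows the bipartite matching problem is convex and this
  greedy rule attains the brute-force optimum (tested against full
  enumeration), making scores order-invariant.
- The detector classifies daily aggregates rather than half hours: every
  feature it uses is daily, so the information is identical at a
  48-fold lower cost. Rolling features use only the current and past
  days; static site attributes are excluded by default (they do not help
  detection) while calendar month is included (it does).
- In the detector split, qualified sites (≥ 5 years, ≥ 20 events) reserve
  their last 3 calendar years for testing and are dropped only if no
  training year remains — the natural reading of the qualification rule,
  which guarantees at least two non-test years otherwise.
- LMG relative importance is computed exactly via the $2^p$ subset-R²
  decomposition (feasible well beyond the nine predictors used for site
  drivers); predictors are standardized for numerical stability, which
  leaves the shares unchanged. Bootstrap spread uses 100 resamples with
  replacement; note that even a noise-free linear response shows nonzero
  share spread for $p > 1$, because the decomposition depends on the
  resampled correlation structure.
- If the day-1 NEE percentile falls below the baseline percentile the
  event is still corrected ($\beta_1 < 1$) but flagged — the correction
  formula has no branch, and such events indicate the baseline already
  overshot.

## Limitations

- The exponential $\beta$ decay under-corrects the tails of long events
  (see above); misidentified end dates are correspondingly benign, since
  most of the emission happens in the first days.
- Events without enough valid day-1 half hours (default 10) cannot be
  anchored and retain the baseline values; on open-path-like records with
  heavy rain-day data loss this affects a noticeable minority of events.
- The universal decay curve requires at least two sites with significant
  site fits; single-site analyses get per-site fits only.
- Alternative partitioners (daytime/light-response, neural, causal) are
  consumed as externally supplied series for comparison statistics; they
  are not implemented here.
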