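# fluxpulse

Detection, characterization and bias correction of rain-induced soil CO₂
pulse events (the Birch effect) in half-hourly dryland eddy-covariance
records.

## The problem

When rain falls on dry soil, heterotrophic respiration surges within hours
and then decays over days — a pulse that appears in net ecosystem exchange
(NEE) as a positive anomaly. The standard night-time flux-partitioning
method models ecosystem respiration (R_eco) as an Arrhenius-type function
of air temperature,

    Reco_NT(j) = R_ref · exp( E0 · ( 1/(T_ref − T0) − 1/(T_air,j − T0) ) )

with T_ref = 288.15 K and T0 = 227.13 K, fitting R_ref in short moving
windows of night-time data. A temperature-response model cannot follow a
water-triggered pulse — rain days are typically *colder*, and post-rain
nights lose most of their valid data to quality screening — so partitioned
R_eco (and hence GPP = R_eco − NEE) is biased low during and just before
pulse events. For dryland sites, where these pulses are a substantial part
of the annual carbon budget, this is a structural bias in widely used flux
products.

`fluxpulse` implements a correction that re-anchors respiration during
events. Pulse decay is modelled by first-order kinetics,

    NEE_i = α · exp(−k · i),        (day 1 = rain day)

fitted per site to the day-indexed maxima of daily mean NEE across events
(α_s = site pulse intensity, k_s = site decay rate), and per event to the
per-day 68th percentiles of half-hourly NEE (with the site-level mean-NEE
array as fallback when the event fit is not significant at p < 0.1). The
correction factor applied to every half hour of event day i is

    β_i = ( NEE_98th_day1 / Reco_NT_98th_day1 ) · exp(−k · (i − 1))
    Reco_corrected(i, j) = β_i · Reco_NT(i, j)

so corrected respiration on day 1 reaches the observed maximum (98th
percentile) NEE — assuming day-1 GPP is negligible after a dry spell, a
deliberately conservative choice — and decays at the empirical rate k.
GPP is then re-derived from NEE = R_eco − GPP, and the days *before* each
event get a 2-day-window R_ref refit (the standard 4-day window leaks the
pulse into the prepulse period).

Around this core the package provides:

- **I/O and QC** — ONEFlux/FLUXNET-style CSV readers/writers, filtering to
  original (non-gap-filled) measurements, dryland site qualification
  (P/PET < 0.65, ≥ 4 years, short/sparse IGBP classes), daily aggregation.
- **Hydrologic indices** — daily daytime evaporative fraction
  EF = LE/(LE+H), antecedent (prepulse) EF/NEE, and the 2-day rewetting
  intensities ΔEF and ΔP.
- **Event catalog** — rule-based candidate screening that mirrors manual
  labelling criteria, per-event length/intensity/size, per-site and pooled
  (universal) decay fits.
- **Detector** — a random-forest classifier of pulse days with the
  site-qualification split (last 3 years test, 80/20 train/validation),
  start-date scoring within ±2 days, size-binned recall and Gini feature
  importances.
- **Drivers** — exact Lindeman–Merenda–Gold (LMG) relative-importance
  decomposition with bootstrap spread, and partial-dependence curves.
- **Synthetic generator** — half-hourly dryland tower records with a known
  respiration/GPP split, injected pulses, EF dynamics, rain-linked cold
  fronts and ONEFlux-like QC provenance, so every stage can be validated
  against ground truth.

## Worked example

```r
library(fluxpulse)

site <- generate_site(synth_config(n_years = 2, seed = 7))
fit  <- fluxpulse(site$flux,
                  events = site$truth$events[c("site_id", "start_date",
                                               "end_date")])
summary(fit)
```

```
Pulse-corrected flux partitioning - summary
  half hours: 35040   E0: 150.0 K
  events: 10 catalogued, 8 corrected
  median decay rate k: 0.221 /day   median intensity: 3.38 umol m-2 s-1
  pulse contribution: 24.3% of respiration, 16.8% of NEP
  night bias (median): -35.2% (NT) -> -16.6% (corrected), one-tailed p = 0.000851
```

The generator injected pulses with E0 = 150 K; the night-window fit
recovers it exactly. Ten events were catalogued; two lacked enough valid
day-1 half hours for the 98th-percentile anchor and fall back to the
uncorrected baseline. During event nights — where NEE itself approximates
respiration — the night-time method runs a −35% median bias; the
correction brings the median to −17% on this single noisy site (pooled
over several sites the corrected median is well under −10%). Per-event
diagnostics live in `fit$events`:

```
  start_date length_days intensity_delta_nee     size    k_used k_source
1 2015-04-02           7            4.820402 24.95188 0.2265727    event
2 2015-06-26           7            5.351422 27.15607        NA     <NA>
3 2015-07-27          11            3.155449 35.29303 0.1177445    event
```

`intensity_delta_nee` is the 2-day-after minus 2-day-before change in
daily mean NEE (µmol CO₂ m⁻² s⁻¹), `size` the summed daily mean NEE over
the event, `k_used`/`k_source` the decay rate entering β and which fit
supplied it.

A thin CLI wraps the same pipeline:

```sh
Rscript inst/cli/fluxpulse.R synth   --out demo_site
Rscript inst/cli/fluxpulse.R correct --site demo_site/halfhourly.csv \
    --events demo_site/events_truth.csv --out demo_corrected
```

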