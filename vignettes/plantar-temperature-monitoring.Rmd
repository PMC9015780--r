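---
title: "Methods: contralateral plantar temperature monitoring, alerting and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contralateral plantar temperature monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtherm)
```

## The measurement model

Inflammation precedes visible tissue injury in the neuropathic foot, and
inflamed tissue is warm. Because feet are nearly bilaterally symmetric, the
skin temperature at a plantar site referenced against the *same site on the
other foot* cancels everything the two feet share — ambient conditions,
circadian physiology, activity — and isolates unilateral processes. The
monitored quantity is therefore the contralateral differential at six
plantar sites (hallux, heel, arch, 1st/3rd/5th metatarsal heads):

$$\Delta T_{\ell}(t) = T^{R}_{\ell}(t) - T^{L}_{\ell}(t), \qquad
\ell \in \{\text{hallux}, \text{heel}, \text{arch}, \text{mts1}, \text{mts3}, \text{mts5}\}$$

computed each minute while **both** socks are worn (a one-sided reading has
no reference and is dropped, not imputed), then averaged per day and site:

$$\bar{D}_{\ell}(d) = \frac{1}{|M_d|}\sum_{t \in M_d} |\Delta T_{\ell}(t)|,$$

with $M_d$ the day's bilaterally worn minutes. A sustained $|\Delta T| >
4\,^\circ\mathrm{F}$ is the clinically established signal of actionable
inflammation; the monitoring rule fires an alert whenever a daily mean
exceeds 4 °F *strictly* at any single site, and flags a hotspot as sustained
once the run of consecutive alert days at one site reaches
`escalation_days` (default 5, the order of the hotspot run observed ahead of
an acute Charcot presentation). Alerts are evaluated on daily means, not raw
minutes, because minute-level spikes are noise-dominated; days backed by
fewer than `min_minutes = 30` minutes are not alert-eligible.

The sign convention is right − left throughout; alerting and statistics use
the magnitude, while the signed trace is preserved for plotting.

## The cohort analysis

For an injured patient the analysis window is the 15 days ending the day
*before* the diagnosis day (diagnosis-day readings may already reflect
clinical handling). For an uninjured control, a 15-day span is drawn
uniformly at random among all spans holding enough data. From each window
exactly 900 bilaterally worn minutes are retained by uniform seeded
subsampling without replacement. How the deployed program selected its 900
minutes for injured patients is not documented; we apply the control arm's
random selection to both arms for symmetry, and expose a
`per_day_quota = 60` mode (60 min/day × 15 days = 900 is suggestive) whose
choice is recorded in the window's `mode` metadata.

Each patient is reduced to one scalar — the mean of $|\Delta T|$ pooled over
the 900 retained minutes and all six sites (`minute_pooled`). Whether the
deployed analysis averaged minutes first or days first is ambiguous
("daily average … for each area"); `mode = "day_first"` provides the
alternative, and the two agree exactly when every day contributes equally.

Patients are the independent units, so the cohort comparison is a Welch
two-sample *t* test on the per-patient scalars, implemented from the
formula:

$$t = \frac{\bar{x}_s - \bar{x}_c}{\sqrt{s_s^2/n_s + s_c^2/n_c}}, \qquad
\nu = \frac{(s_s^2/n_s + s_c^2/n_c)^2}
           {\frac{(s_s^2/n_s)^2}{n_s-1} + \frac{(s_c^2/n_c)^2}{n_c-1}},$$

with a two-sided $p$ from the $t_\nu$ distribution and
$\text{CI} = \bar{x}_s - \bar{x}_c \pm t_{\nu,1-\alpha/2}\,\mathrm{SE}$.
An established implementation is used **only** as an independent oracle in
the test suite. `run_cohort_comparison(pseudoreplicate_minutes = TRUE)`
instead pools every retained minute into the test; with ~5400 correlated
"observations" per patient this inflates $|t|$ enormously and is labeled
pseudo-replication in the report — it exists to illustrate how an extreme
$t$ with a df near the pooled-minute count can arise, not for inference.

## What the synthetic generator states

No monitoring registry data are distributable, so the package carries a
generator whose *defaults are a stated world*, fixed once:

| parameter | default | rationale |
|---|---|---|
| span | 135 days | length of the monitoring program's observation period |
| cohorts | 5 study / 26 control | the program's case-control design |
| wear | 480 ± 60 min/day, one contiguous block at a uniform start | "worn throughout the day"; simplest model — refinements are common-mode and cancel |
| baseline | 85 ± 1.5 °F per patient | in-sock skin-contact temperature |
| circadian | 1.5 °F sinusoid, 1440-min period, shared by both feet | common-mode by premise of the method |
| drift | random walk, 0.3 °F/day, shared | day-to-day physiological/ambient variation |
| sensor noise | 1.95 °F per sensor per minute, independent | **calibrated**, see below |
| ambient | 72 °F when unworn | sock off ⇒ room temperature |

Every common-mode term (baseline, site offsets, circadian, drift) is shared
by both feet, so absent injury the minute differential is exactly
$N(0, \sigma\sqrt{2})$ with $\sigma$ the per-sensor noise sd — the expected
differential is identically zero, which is the premise the contralateral
method rests on. An injury adds a linear ramp (0 at onset to `peak_offset`
at `onset_day + ramp_days`, sustained thereafter) to the affected foot's
affected sites; figure traces of real events show gradual rise then
persistence, and the exact shape is otherwise unspecified.

**Calibration** (`scripts/calibrate.R`, closed form, run once before any
acceptance measurement): the null window statistic has expectation
$E|N(0,\sigma\sqrt 2)| = \sigma\sqrt{2}\cdot\sqrt{2/\pi}$; setting this to
the program's printed control mean of 2.20 °F gives $\sigma = 1.95$ °F. The
five injury archetypes (diffuse Charcot, focal hallux blister, diffuse
osteomyelitis, focal mts5 ulcer with adjacent involvement, diffuse DVT)
get peak offsets (7, 8, 4.8, 10, 8 °F) chosen from the folded-normal mean
formula so the expected study-cohort mean is ≈3.60 °F against the printed
3.59 °F. These are configuration values, not code.

**What the generator deliberately does not reproduce.** The printed
*between-patient* SDs (1.42 study, 1.31 control) are unattainable in this
stated world: the null-symmetry requirement (zero expected differential for
*every* uninjured stream) forbids fixed per-patient asymmetries, and the
mean of 5400 folded-normal draws concentrates tightly, so synthetic control
statistics cluster within a few hundredths of 2.20. Real feet carry
persistent structural asymmetries that this generator intentionally omits.
Consequently a green cohort-comparison test establishes that the *pipeline*
recovers the statistics implied by its inputs — not that real patients
behave like the generator. Similarly out of scope: biophysical heat
transfer, footwear/activity covariates, and sensor dropout beyond
worn/not-worn.

## Numerical and design choices

- **Time** is (day index, minute-of-day), 0-based, no calendars or
  timezones. Temperatures are °F end to end; no unit conversion exists in
  the core.
- **Wear day**: a day with ≥ 30 bilaterally worn minutes; the inclusion
  filter keeps patients with *strictly more than* 50 wear days, reading the
  protocol's "greater than" literally.
- **Determinism**: every sampling operation takes a seed and is a pure
  function of (inputs, parameters, seed); per-patient stream and window
  seeds are derived by hashing the master seed with the patient id, so
  generation order is irrelevant. Seeding is done in a local RNG scope that
  restores the caller's `.Random.seed`.
- **Degenerate inputs**: a never-worn stream yields empty differentials
  (not an error); a stream in which exactly one foot never appears is
  rejected — contralateral analysis on a unilateral record is not
  meaningful (no amputation handling). Both cohort variances equal to zero
  makes the Welch statistic undefined; the comparison is then reported as
  degenerate rather than erroring the whole report.
- **Rounding**: demographics percentages round half away from zero to
  integers, matching clinical-table convention.
- **Alert runs** break across gaps in the day index: a non-alert or unworn
  day resets the consecutive-day counter.

## Known limitations and irreproducible printed statistics

Three printed statistics of the motivating analysis are internally
inconsistent and are deliberately **not** targets anywhere in this package:
a reported $t = -71.4$ with $df = 39$ is incompatible with 5-vs-26
patient-level units (but is of the order produced by minute-level pooling —
see the pseudo-replication mode); a reported 95% CI of 0.859–1.20 excludes
the reported mean difference of 1.4 °F; and the abstract's SDs (3.0/2.5)
disagree with the results section's (1.42/1.31). The cohort means and the
demographics table are reproduced; those three statistics are documented as
irreproducible. A "paired" test is likewise undefinable for unpaired 5-vs-26
cohorts; Welch is the implemented method.

One calibration note on the Welch test at the study's own design: with
$n_s = 5$ the Welch–Satterthwaite approximation is mildly liberal (empirical
size ≈ 0.055 at nominal 0.05 — reproduced identically by the independent
reference implementation). The type-I acceptance check therefore asserts
calibration at a balanced 15 v 16 split of the same 31 patients, and
separately bounds the 5 v 26 size below 0.08. A related pitfall surfaced in
testing: re-seeding each simulation replicate with *consecutive* integers
correlates Mersenne–Twister streams enough to bias an empirical rejection
rate upward by a percentage point; replicated simulations should consume
one continuous seeded stream.

## A small worked run

```{r demo, eval = FALSE}
cfg <- pipeline_config(
  generator = generator_config(n_study = 2, n_control = 4, days = 70,
                               seed = 11),
  min_wear_days = 30, seed = 11
)
report <- run_full_demo(cfg, "demo_out", write_streams = FALSE)
report
```

The artifact directory contains the registry, daily differentials, alert
events, windows with explicit retained-minute lists, the JSON report, and
per-patient trace plots shaded by baseline / pre-injury / active period;
`manifest.json` records the config hash and seed, and re-running with the
same configuration reproduces every file byte for byte.
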