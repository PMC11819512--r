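---
title: "Methods: classifying and modelling harbour porpoise social click trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and modelling harbour porpoise social click trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(porpoisesocial)
```

## The problem

Harbour porpoises produce narrow-band high-frequency (NBHF) clicks for both
echolocation and communication. In click-detector (F-POD/C-POD style)
exports, foraging trains are recognizable by their three-phase rate
profile — slow search (instantaneous rate below 200 c/s, many inter-click
intervals above 10 ms), accelerating approach, terminal feeding buzz —
whereas social calls appear as short, discrete bursts at 200–1,000 clicks/s
that repeat within a few seconds and lack foraging structure. Separating
the two from rate profiles alone is the core methodological difficulty:
the inter-click-interval ranges overlap, so a rule set rather than a single
threshold is required. This package operationalizes the visual marking
rules analysts apply to detector displays, so the procedure is
deterministic, auditable and testable against simulated ground truth.

## Data model and units

Clicks carry a time in seconds since record start and a centroid frequency
in kHz; all trains of one site share the clock, whose absolute origin (a
`POSIXct`) drives every wall-clock computation (minutes for DPM, hour of
day, month). Instantaneous rate is the reciprocal of each inter-click
interval; a train's mean rate is $(n-1)/\text{duration}$. Analysis frames
are a fixed 15-s grid anchored at the record start: a grid (rather than a
sliding window) makes frame membership reproducible, and anchoring at
record start rather than clock minutes is an arbitrary but documented
choice — the alternative shifts frame boundaries by at most one frame and
does not change any train-level quantity.

## The candidate filter

Mirroring detector view settings, candidates must have mean rate
$\ge 100$ c/s and mean frequency in $[105, 140]$ kHz, and must intersect a
frame holding at least 256 clicks (all trains pooled — frame eligibility is
a property of the display, not of one train). "At least" and "between" are
read inclusively. The filter is monotone: relaxing any threshold can only
add candidates, which the tests assert.

## Operationalizing the social criteria

The four marking rules are analyst judgments; each needs a quantitative
proxy. The tunable tolerances live in `social_criteria()`:

* **Searching phase (a, part 1).** "No visible searching phase below
  200 c/s" becomes: fail if more than 10% of instantaneous rates fall below
  200 c/s (`max_subthreshold_fraction = 0.1`), or any contiguous
  sub-threshold run exceeds 10 intervals. A single jittered slow interval
  inside a fast burst should not veto a mark; a visible slow phase is
  either a sizeable fraction or a sustained run.
* **Terminal buzz (a, part 2).** An upsweep is a robustly rising terminal
  trend: over the last 10 intervals (`buzz_trend_window`), the Theil–Sen
  slope must be positive, a one-sided sign test on successive differences
  must give p < 0.05, and the terminal rate (mean of the last three) must
  exceed the train's median. The robust slope plus sign test resists
  single-interval jitter; the median condition keeps rise–fall (mushroom)
  profiles, whose terminal rate is low, from being mistaken for buzzes.
  Trains shorter than the window cannot be assessed and are scored
  not-buzzing with a note.
* **Discreteness (b).** "Not part of a longer train" becomes a silence gap
  of at least 150 ms before the first and after the last click, relative to
  every other click in the record, with no foreign click inside the span.
  150 ms is roughly 15 times the 10-ms ICI boundary between social-rate
  and foraging-rate clicking — long enough that consecutive bursts of one
  longer train fail it, short enough that genuinely separate bursts (gaps
  of several hundred ms) pass.
* **Repetition (c).** At least two mutually similar bursts within one
  eligible 15-s frame. Similarity = duration ratio in $[0.5, 2]$ and
  Pearson correlation $\ge 0.7$ between rate profiles reduced to 24 bin
  means on normalized time. Bin averaging (rather than raw interpolation)
  suppresses interval-level jitter so that two draws of the same shape
  correlate highly while a mushroom and a wiggle do not. Repetition of
  *shape*, not of pattern label, is required — whether a mushroom may
  repeat with a wiggle is not specified by the marking rules, and profile
  correlation settles it naturally (they do not correlate).
* **Rate band (d).** Mean rate in $[200, 1000]$ c/s inclusive. The
  200 c/s lower bound is the operational marking criterion; the narrower
  250–1,000 c/s figure reported from captive studies is used by the
  *generator* defaults instead, so generated positives sit inside the
  classifier's acceptance band rather than on its boundary.

Any criterion failure vetoes the social mark and is recorded
(`failed_criteria`), mirroring the conservative rule that anything
resembling foraging is left unmarked. Determinism of the whole
classification is asserted in the tests, and tightening any tolerance can
only reduce the social count (also asserted).

**Pattern labels.** Social trains are labelled from the smoothed binned
profile by counting local maxima with peak-to-valley persistence at least
25% of the profile range: one maximum = mushroom, two or more = wiggle,
none (flat) = none. The persistence filter is what makes the count robust:
raw jitter produces many small extrema but none that deep.

## The synthetic-data generator

`generate_deployment()` is first-class, tested code: it defines the study
conditions under which the classifier and models are validated.

* **Encounter process.** Hourly encounter counts are negative-binomial
  (gamma-mixed Poisson, size `overdispersion_k = 2`) around a mean
  $\mu_h = \frac{\lambda}{24}\,d(h)\,m(\text{month})$ with
  $\lambda = 20$ encounters/day, a mean-one cosine diel factor
  $d(h) = 1 + 0.8\cos(2\pi (h - 23)/24)$ (darkness-peaked), and mean-one
  monthly weights peaking in May with a smaller October rise. Encounter
  times are uniform within their hour; encounters within 60 s of a
  predecessor are thinned so trains stay temporally discrete. Each
  encounter is social with probability 0.2. These defaults are a
  plausible mid-density porpoise monitoring site; they are set once and
  the tests run against them.
* **Foraging trains.** Search rate drawn from 20–100 c/s for 4–9 s,
  geometric ramp to 300 c/s over 1.5–3 s, buzz rising to 300–600 c/s for
  0.5–1.2 s; inter-click intervals get multiplicative lognormal jitter
  (sd 0.12). Mean frequencies are drawn in 110–135 kHz so candidates pass
  the frequency filter and the classifier, not the filter, must reject
  them.
* **Social sequences.** 2–4 bursts sharing one shape per sequence —
  mushroom $r(u) = b + (p-b)\sin(\pi u)$ or wiggle
  $r(u) = m - a\cos(2\pi k u)$, $k \in \{2,3\}$ (which starts and ends at
  its minimum, so a wiggle never ends rising like a buzz) — with rates in
  250–900 c/s, durations 0.5–1.2 s and silence gaps 0.4–2.5 s. The whole
  group is placed inside a single 15-s analysis frame: repetition is
  defined per frame, so a generator that split groups across frame
  boundaries would make its own truth labels unattainable. The easy-mode
  preset (`scenario_easy()`: 400–800 c/s, 3–4 repeats, lower jitter) is
  the self-consistency scenario on which recall must be exactly 1.

What the generator does *not* emulate: propagation loss and detection
range, ambient noise or vessel masking, multiple animals vocalizing
simultaneously (overlapping trains), detector misclassification upstream,
and duty-cycle gaps. Perfect precision/recall on the benchmark therefore
validates the internal consistency of criteria and generator — it does not
promise that performance on field data, where overlap and masking blur the
criteria, will match.

## DPM aggregation and proportions

A minute is social-positive if any social train clicks in it; total DPM is
the union of social- and nonsocial-positive minutes (a minute positive for
both counts once — "total" means all detections, and union avoids double
counting). Hours inside the record span are reported even when zero; time
outside the span is absent rather than zero, so equipment gaps do not
dilute rates. DPM is invariant to splitting a train within a minute
(tested). Percentages are reported to one decimal, matching how such
results are printed; internal hours are 0–23 with the 1–24 display
convention applied only at presentation. The inter-rater quality-control
comparison is directional set overlap of marked social minutes.

## Statistical stage

Shapiro–Wilk (via `stats::shapiro.test`) decides parametric vs rank tests;
Kruskal–Wallis (via `stats::kruskal.test`) compares hourly social-DPM
proportions across hours, months and years; Dunn's post-hoc z-tests are
computed from pooled midranks with tie correction and Bonferroni adjustment
over all pairs within the tested factor (implemented here — the test suite
checks both KW and Dunn exhaustively against an independent counting-based
rank oracle on all small instances). VIF uses the defining regression
$\mathrm{VIF}_j = 1/(1-R^2_j)$ with cutoff 5, cross-checked against
`car::vif`.

The DPM models are negative-binomial GAMs fitted with `mgcv::bam` (log
link): cyclic cubic smooths with $k = 8$ for hour (knots wrapping 0/24) and
$k = 6$ for month (knots 0.5/12.5 so December joins January), a year
factor when multiple years are observed, and fast-REML smoothing-parameter
selection. Basis sizes are conventional for one daily and one annual
cycle; cyclic continuity at the period boundary is exact by construction
and asserted in the tests. If the lag-1 autocorrelation of the working
residuals exceeds 0.2 the model is refitted with `bam`'s AR1 structure at
the estimated $\rho$. Backward selection removes the least significant
term with p > 0.05, refits, and stops when all retained terms are
significant, reporting the AIC trajectory; removing every term returns the
intercept-only model with a warning. Hour/month "peak" summaries evaluate
the fitted smooth only over the observed covariate range — a half-year
record does not constrain the unobserved half of the seasonal cycle.

Two modelling modes exist because "per response, test hour, month and year"
can be read as one joint model or separate single-covariate models: the
joint model is the default (`gam_spec(terms = ...)` fits any subset, so the
separate reading is available by passing one term at a time).

## Numerical and degenerate-input choices

Single-click trains are degenerate for every rate quantity and raise
errors; non-increasing timestamps are rejected at construction. Flat rate
profiles break profile correlation (zero variance), so two flat bursts are
deemed similar when their mean rates are within a factor 1.5. Groups with
zero total DPM give an undefined percentage, reported as `NA`. Zero-variance
series are rejected by the autocorrelation and normality functions.
Singular VIF regressions report `Inf` and are flagged. GAM non-convergence
raises an explicit error rather than returning a silent misfit.

## Problem sizes used by the tests and acceptance script

The validation suite simulates 90 days (~1,800 trains, ~1.5 M clicks) for
the benchmark, 30 days for the easy/foraging-only scenarios, 180 days for
seasonal-peak recovery, 4,000 hourly counts for dispersion recovery, and
1,000 null replicates for the Kruskal–Wallis size check; the exhaustive
rank-oracle comparison covers every assignment of up to 12 values into two
groups and up to 8 into three. These sizes give stable statistics while
keeping a full run in the minutes range on a single core.

## Known limitations

* The criteria are tuned proxies for analyst judgment; the tolerance
  defaults (10% sub-threshold fraction, 150 ms gap, 0.7 similarity) are
  documented assumptions, not fitted quantities.
* Mushroom/wiggle shape parameters are assumptions: the source categories
  are visual, with no published quantitative shape parameters.
* The repetition criterion is frame-scoped; bursts repeating across a
  frame boundary are not credited (the generator avoids this; field data
  may not).
* Field DPM values and model fits are not reproducible from this package —
  no raw field data are included; published count totals are used only as
  arithmetic inputs.
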