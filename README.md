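# porpoisesocial

Quantifying social acoustic behaviour of harbour porpoises from passive
acoustic monitoring (PAM) click-train records.

Harbour porpoises echolocate with narrow-band high-frequency (NBHF) clicks
(~105–140 kHz). Foraging click trains have a characteristic shape: a slow
"searching" phase (instantaneous rates below 200 clicks/s, inter-click
intervals often above 10 ms), an accelerating "approach", and a terminal
feeding buzz in which the click rate sweeps sharply upward. Social
communication, by contrast, appears as *discrete, repeated, high-rate bursts*
(200–1,000 clicks/s) with no search phase and no buzz, falling mainly into
two rate-profile shapes: unimodal rise–fall "mushrooms" and oscillating
"wiggles". This package turns those visual marking rules into an automated,
testable pipeline for click-detector exports (e.g. F-POD/C-POD style
train-segmented data), and provides a truth-labelled synthetic-deployment
generator to validate every stage.

## What the pipeline computes

For a record of click trains with times \(t_1 < t_2 < \dots < t_n\) (seconds)
the instantaneous rate over each inter-click interval is \(r_i = 1/(t_{i+1} -
t_i)\) c/s and the mean rate is \((n-1)/(t_n - t_1)\).

1. **Candidate filter** — keep trains with mean rate ≥ 100 c/s and mean
   centroid frequency in [105, 140] kHz; scan only fixed 15-s frames holding
   ≥ 256 clicks (all bounds inclusive).
2. **Social criteria (a)–(d)** — a candidate is marked social only if it
   (a) shows no foraging structure: no searching phase (more than 10% of
   rates, or a contiguous run of > 10 intervals, below 200 c/s) and no
   terminal buzz (robust rising trend — Theil–Sen slope with a sign test —
   over the last 10 intervals ending above the train's median rate);
   (b) is discrete: ≥ 150 ms of silence on both sides relative to every
   other click in the record;
   (c) repeats: ≥ 2 bursts in one eligible frame with duration ratio in
   [0.5, 2] and correlation ≥ 0.7 between length-normalized rate profiles;
   (d) has mean rate in [200, 1,000] c/s.
   Any failure vetoes the social mark (conservative by design). Social
   trains are then labelled mushroom (one prominent rate maximum) or wiggle
   (two or more).
3. **Detection-positive minutes (DPM)** — a clock minute is social-positive
   if any social train clicks in it, likewise non-social; the total is the
   union. DPM are tabulated per hour and summarized as the percentage of
   social DPM by month, hour and year.
4. **Temporal models** — Shapiro–Wilk, Kruskal–Wallis and Dunn–Bonferroni
   tests on hourly social-DPM proportions; VIF collinearity screen (cutoff
   5); negative-binomial GAMs of hourly DPM counts with cyclic cubic
   smooths of hour (period 24) and month (period 12), a year factor, fast
   REML smoothing, an AR1 residual structure when the lag-1 residual
   autocorrelation exceeds 0.2, and backward selection of non-significant
   terms (p > 0.05).

The synthetic generator (`generate_deployment()`) draws encounters from an
inhomogeneous process — negative-binomial hourly counts around a mean with a
cosine diel bump (default peak 23:00) and monthly weights (default May peak,
smaller fall rise) — and renders each encounter as either a foraging train
or a repeated social burst group, with per-train ground truth.

## Worked example

The `analysis/` scripts run the whole study on a simulated 90-day record
(seed 20), writing tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R   # simulate the benchmark deployment
Rscript analysis/02_classify.R   # filter + social criteria vs truth
Rscript analysis/03_dpm.R        # DPM aggregation and proportions
Rscript analysis/04_models.R     # rank tests, VIF, ACF, NB-GAMs
```

Output from those runs:

```
simulated 90 days: 1810 trains (777 social, 1033 foraging), 1553081 clicks
filter: 1656/518400 frames eligible, 1378/1810 trains in candidate view
classification vs truth: precision 1.000, recall 1.000 (tp 777, fp 0, fn 0)
overall: 267 social DPM of 1497 total = 17.8% social
diel: social DPM count peaks at hour 21
published totals: 2,619/49,811 social DPM = 5.3%
published annual totals 15,006 -> 6,948: -53.7% change
NB-GAM for dpm_social: AIC = 1620.8, adj R2 = 0.030, dev expl = 6.5%, theta = 4.50
  fitted hour smooth peaks at 21.5 h
NB-GAM for dpm_nonsocial: ... fitted hour smooth peaks at 23.0 h
```

Reading this: the classifier recovers every truth-social train with no
false marks on this scenario; the simulated record is 17.8% social DPM
(the generator's social fraction is 0.2 — higher than the published field
value of 5.3%, which the proportion operation reproduces from the published
hourly totals); both fitted hour smooths peak near the configured 23:00
encounter-intensity maximum.

Equivalent single call: `run_pipeline(run_config(...))` writes every
artifact (clicks, truth, classifications, DPM, proportions, model JSON,
resolved YAML config, markdown report) into one directory.

## Click-export CSV dialect

One row per click, UTF-8, RFC-4180: `datetime_utc` (record origin,
`YYYY-MM-DDTHH:MM:SSZ`), `site`, `train_id`, `click_time_offset_s` (seconds
since origin), `freq_khz`. `read_clicks()` validates the schema strictly
and reports the first offending row. Truth tables are
`train_id,true_class,true_pattern`; hourly DPM tables are
`site,date,hour,month,year,dpm_social,dpm_nonsocial,dpm_total`.

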