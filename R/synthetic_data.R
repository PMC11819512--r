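#' Scenario configuration for synthetic deployments
#'
#' Bundles every tunable of the synthetic-data generator: the encounter
#' process (daily base rate, cosine diel bump peaking in darkness, monthly
#' weights peaking in spring with a smaller fall rise, negative-binomial
#' overdispersion of hourly counts), the foraging train shape
#' (search -> approach -> terminal buzz), and the social burst shape
#' (repeated 15-s-frame-confined high-rate bursts, "mushroom" rise-fall or
#' "wiggle" oscillating rate profiles).
#'
#' Defaults emulate a porpoise monitoring record: ~20 encounters/day, diel
#' peak at hour 23, May-peaked month weights, 20% social encounters, social
#' bursts at 250-1000 c/s (deliberately inside the classifier's 200-1000
#' acceptance band), foraging search below 200 c/s with a rising buzz.
#'
#' @param seed Integer RNG seed; the only source of randomness.
#' @param duration_days Length of the simulated record in days.
#' @param encounters_per_day_base Mean encounters per day before diel and
#'   monthly modulation.
#' @param diel_peak_hour Hour (0-23) of peak encounter intensity.
#' @param diel_amplitude Relative amplitude of the cosine diel bump, in
#'   `[0, 1]`; 0 gives a flat diel profile.
#' @param month_weights 12 positive weights (Jan..Dec), internally normalized
#'   to mean 1.
#' @param social_fraction Probability an encounter is social, in `[0, 1]`.
#' @param overdispersion_k Negative-binomial size of hourly encounter counts
#'   (gamma-mixed Poisson); smaller = more overdispersed.
#' @param search_rate_range,search_duration_range Foraging search phase:
#'   click rate band (c/s) and duration band (s); durations must be > 0.
#' @param approach_duration_range Foraging approach phase duration band (s).
#' @param buzz_rate_range,buzz_duration_range Terminal feeding-buzz rate band
#'   (c/s) and duration band (s).
#' @param burst_rate_range Social burst instantaneous-rate band (c/s).
#' @param burst_duration_range Social burst duration band (s).
#' @param n_repeats_range Integer band for the number of repeated bursts per
#'   social sequence; minimum must be >= 2.
#' @param gap_range Silence gap band between bursts of one sequence (s).
#' @param pattern_mix Named probabilities for `mushroom` and `wiggle` shapes.
#' @param ici_jitter_sd Lognormal sd of multiplicative inter-click-interval
#'   jitter.
#' @param freq_mean_range Band for per-train mean centroid frequency (kHz).
#' @param frame_length Analysis frame length (s) the generator confines each
#'   social sequence to.
#' @param site Site label.
#' @param origin Absolute start time of the record (`POSIXct`); diel and
#'   monthly logic use this clock.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            duration_days = 90L,
                            encounters_per_day_base = 20,
                            diel_peak_hour = 23,
                            diel_amplitude = 0.8,
                            month_weights = c(0.40, 0.35, 0.60, 0.85, 1.00, 0.90,
                                              0.70, 0.50, 0.55, 0.75, 0.55, 0.45),
                            social_fraction = 0.2,
                            overdispersion_k = 2,
                            search_rate_range = c(20, 100),
                            search_duration_range = c(4, 9),
                            approach_duration_range = c(1.5, 3),
                            buzz_rate_range = c(300, 600),
                            buzz_duration_range = c(0.5, 1.2),
                            burst_rate_range = c(250, 900),
                            burst_duration_range = c(0.5, 1.2),
                            n_repeats_range = c(2L, 4L),
                            gap_range = c(0.4, 2.5),
                            pattern_mix = c(mushroom = 0.6, wiggle = 0.4),
                            ici_jitter_sd = 0.12,
                            freq_mean_range = c(110, 135),
                            frame_length = 15,
                            site = "site1",
                            origin = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  cfg <- list(seed = as.integer(seed), duration_days = as.integer(duration_days),
              encounters_per_day_base = encounters_per_day_base,
              diel_peak_hour = diel_peak_hour, diel_amplitude = diel_amplitude,
              month_weights = month_weights, social_fraction = social_fraction,
              overdispersion_k = overdispersion_k,
              search_rate_range = search_rate_range,
              search_duration_range = search_duration_range,
              approach_duration_range = approach_duration_range,
              buzz_rate_range = buzz_rate_range,
              buzz_duration_range = buzz_duration_range,
              burst_rate_range = burst_rate_range,
              burst_duration_range = burst_duration_range,
              n_repeats_range = as.integer(n_repeats_range),
              gap_range = gap_range, pattern_mix = pattern_mix,
              ici_jitter_sd = ici_jitter_sd, freq_mean_range = freq_mean_range,
              frame_length = frame_length, site = site, origin = origin)
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2 && !any(is.na(r)) && r[1] <= r[2]
  for (f in c("search_rate_range", "search_duration_range",
              "approach_duration_range", "buzz_rate_range",
              "buzz_duration_range", "burst_rate_range",
              "burst_duration_range", "n_repeats_range", "gap_range",
              "freq_mean_range")) {
    if (!rng_ok(cfg[[f]])) stop("scenario_config: ", f, " must be an ordered pair")
  }
  if (cfg$n_repeats_range[1] < 2L)
    stop("scenario_config: social sequences must repeat at least twice (n_repeats >= 2)")
  if (cfg$social_fraction < 0 || cfg$social_fraction > 1)
    stop("scenario_config: social_fraction must lie in [0, 1]")
  if (cfg$diel_amplitude < 0 || cfg$diel_amplitude > 1)
    stop("scenario_config: diel_amplitude must lie in [0, 1]")
  if (length(cfg$month_weights) != 12 || any(cfg$month_weights <= 0))
    stop("scenario_config: month_weights must be 12 positive values")
  if (cfg$overdispersion_k <= 0) stop("scenario_config: overdispersion_k must be > 0")
  invisible(cfg)
}

#' Easy-separation scenario preset
#'
#' High-rate (400-800 c/s), long, 3-4 times repeated social bursts with wide
#' silence gaps and low jitter: every generated social train should satisfy
#' all classifier criteria, giving 100% recall by construction.
#'
#' @param seed RNG seed.
#' @param duration_days Record length in days.
#' @param ... Further overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_easy <- function(seed = 1L, duration_days = 30L, ...) {
  scenario_config(seed = seed, duration_days = duration_days,
                  burst_rate_range = c(400, 800),
                  burst_duration_range = c(0.6, 1.2),
                  n_repeats_range = c(3L, 4L),
                  gap_range = c(0.5, 2),
                  ici_jitter_sd = 0.08, ...)
}

# mean-1 cosine diel modulation factor for hour-of-day h (0-23)
diel_factor <- function(h, peak_hour, amplitude) {
  1 + amplitude * cos(2 * pi * (h - peak_hour) / 24)
}

# multiplicative ICI jitter, vectorized
ici_jitter <- function(n, sd) exp(stats::rnorm(n, 0, sd))

# click times from a vector of target instantaneous rates (c/s)
times_from_rates <- function(rates, jitter_sd) {
  icis <- (1 / rates) * ici_jitter(length(rates), jitter_sd)
  cumsum(c(0, icis))
}

# per-click centroid frequencies around a train-level mean
draw_freqs <- function(n, cfg) {
  mu <- stats::runif(1, cfg$freq_mean_range[1], cfg$freq_mean_range[2])
  pmax(stats::rnorm(n, mu, 1), 90)
}

#' Generate one foraging click train
#'
#' Three-phase rate profile: a slow search phase below 200 c/s with long
#' inter-click intervals (many over 10 ms), a geometric-ramp approach, and a
#' terminal feeding buzz whose rate rises into the buzz band. Consumes the
#' global RNG stream; seed it (or call within [generate_deployment()]) for
#' reproducibility.
#'
#' @param cfg A `scenario_config`.
#' @param id Train id.
#' @return A `click_train` starting at time 0.
#' @export
generate_foraging_train <- function(cfg, id = "forage1") {
  validate_scenario_config(cfg)
  if (cfg$search_duration_range[1] <= 0)
    stop("degenerate config: search phase duration must be positive")
  r_search <- stats::runif(1, cfg$search_rate_range[1], cfg$search_rate_range[2])
  d_search <- stats::runif(1, cfg$search_duration_range[1], cfg$search_duration_range[2])
  n_search <- max(3L, round(d_search * r_search))
  rates_search <- r_search * exp(stats::rnorm(n_search, 0, 0.10))

  r_buzz0 <- cfg$buzz_rate_range[1]
  d_appr <- stats::runif(1, cfg$approach_duration_range[1], cfg$approach_duration_range[2])
  n_appr <- max(3L, round(d_appr * (r_search + r_buzz0) / 2))
  rates_appr <- exp(seq(log(r_search), log(r_buzz0), length.out = n_appr))

  r_buzz1 <- stats::runif(1, mean(cfg$buzz_rate_range), cfg$buzz_rate_range[2])
  d_buzz <- stats::runif(1, cfg$buzz_duration_range[1], cfg$buzz_duration_range[2])
  n_buzz <- max(12L, round(d_buzz * (r_buzz0 + r_buzz1) / 2))
  rates_buzz <- exp(seq(log(r_buzz0), log(r_buzz1), length.out = n_buzz))

  rates <- c(rates_search, rates_appr, rates_buzz)
  times <- times_from_rates(rates, cfg$ici_jitter_sd)
  click_train(id, times, draw_freqs(length(times), cfg),
              site = cfg$site, origin = cfg$origin)
}

# shape parameters shared by all bursts of one social sequence
draw_burst_shape <- function(cfg) {
  lo <- cfg$burst_rate_range[1]; hi <- cfg$burst_rate_range[2]
  pattern <- sample(names(cfg$pattern_mix), 1, prob = cfg$pattern_mix)
  if (pattern == "mushroom") {
    base <- stats::runif(1, lo, lo + 0.2 * (hi - lo))
    peak <- stats::runif(1, base + 0.3 * (hi - base), hi)
    shape <- list(pattern = pattern, base = base, peak = peak)
  } else {
    amp <- stats::runif(1, 0.15, 0.30) * (hi - lo)
    mid <- stats::runif(1, lo + amp, hi - amp)
    shape <- list(pattern = pattern, mid = mid, amp = amp,
                  cycles = sample(2:3, 1))
  }
  shape$duration <- stats::runif(1, cfg$burst_duration_range[1],
                                 cfg$burst_duration_range[2])
  shape
}

# target rate at burst phase u in [0,1]; mushroom = unimodal rise-fall,
# wiggle = oscillation starting and ending at its minimum (never ends rising)
burst_rate_curve <- function(shape, u) {
  if (shape$pattern == "mushroom") {
    shape$base + (shape$peak - shape$base) * sin(pi * u)
  } else {
    shape$mid - shape$amp * cos(2 * pi * shape$cycles * u)
  }
}

generate_burst_times <- function(cfg, shape) {
  # per-burst perturbation keeps repeats similar but not identical
  dur <- shape$duration * stats::runif(1, 0.9, 1.1)
  mean_rate <- if (shape$pattern == "mushroom") {
    shape$base + (shape$peak - shape$base) * 2 / pi
  } else shape$mid
  n <- max(20L, round(dur * mean_rate))
  u <- (seq_len(n) - 0.5) / n
  rates <- burst_rate_curve(shape, u) * stats::runif(1, 0.95, 1.05)
  times_from_rates(rates, cfg$ici_jitter_sd)
}

#' Generate one social click-train sequence
#'
#' A sequence of `n_repeats >= 2` short high-rate bursts sharing one shape
#' ("mushroom": single rate maximum; "wiggle": >= 2 rate maxima), separated
#' by silence gaps, with the whole group confined to less than one 15-s
#' analysis frame. Burst rates stay inside `burst_rate_range`, there is no
#' terminal buzz trend, and gaps exceed the classifier's discreteness gap.
#'
#' @param cfg A `scenario_config`.
#' @param id_prefix Prefix for burst train ids (`<prefix>_b1`, ...).
#' @param n_repeats Number of bursts; defaults to a draw from
#'   `cfg$n_repeats_range`. Must be >= 2.
#' @return List of `click_train` bursts; first burst starts at time 0. The
#'   shared pattern name is attached as attribute `"pattern"`.
#' @export
generate_social_sequence <- function(cfg, id_prefix = "social1", n_repeats = NULL) {
  validate_scenario_config(cfg)
  if (is.null(n_repeats))
    n_repeats <- sample(cfg$n_repeats_range[1]:cfg$n_repeats_range[2], 1)
  if (n_repeats < 2) stop("social sequences must contain at least 2 repeated bursts")

  shape <- draw_burst_shape(cfg)
  bursts_t <- lapply(seq_len(n_repeats), function(i) generate_burst_times(cfg, shape))
  gaps <- stats::runif(n_repeats - 1, cfg$gap_range[1], cfg$gap_range[2])

  # compress gaps if needed so the whole group fits strictly inside one frame
  durs <- vapply(bursts_t, function(t) t[length(t)], numeric(1))
  max_span <- cfg$frame_length - 0.6
  if (sum(durs) + sum(gaps) > max_span) {
    gap_budget <- max_span - sum(durs)
    if (gap_budget <= 0.2 * (n_repeats - 1))
      stop("burst durations too long to repeat within one analysis frame")
    gaps <- gaps * (gap_budget / sum(gaps))
  }

  starts <- cumsum(c(0, durs[-n_repeats] + gaps))
  out <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    out[[i]] <- click_train(sprintf("%s_b%d", id_prefix, i),
                            starts[i] + bursts_t[[i]],
                            draw_freqs(length(bursts_t[[i]]), cfg),
                            site = cfg$site, origin = cfg$origin)
  }
  attr(out, "pattern") <- shape$pattern
  out
}

# hourly expected encounter intensity over the record, with calendar covariates
hourly_intensity <- function(cfg) {
  n_hours <- cfg$duration_days * 24L
  t0 <- cfg$origin + (seq_len(n_hours) - 1L) * 3600
  lt <- as.POSIXlt(t0)
  mw <- cfg$month_weights / mean(cfg$month_weights)
  data.frame(
    hour_index = seq_len(n_hours),
    hour_of_day = lt$hour,
    month = lt$mon + 1L,
    mu = cfg$encounters_per_day_base / 24 *
      diel_factor(lt$hour, cfg$diel_peak_hour, cfg$diel_amplitude) *
      mw[lt$mon + 1L]
  )
}

#' Generate a full truth-labelled synthetic deployment
#'
#' Encounter times follow an inhomogeneous process: hourly counts are
#' negative-binomial (gamma-mixed Poisson, size `overdispersion_k`) around a
#' mean with multiplicative diel (cosine bump at `diel_peak_hour`) and
#' monthly modulation; encounter times are uniform within their hour, and
#' encounters within 60 s of a predecessor are thinned away so trains stay
#' temporally discrete. Each encounter is social with probability
#' `social_fraction` (one repeated-burst sequence, placed wholly inside one
#' 15-s analysis frame) or foraging (one search-approach-buzz train).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A `scenario_config`.
#' @return A `deployment` list: `trains` (list of `click_train`), `truth`
#'   (`data.frame` train_id, true_class, true_pattern), `dpm_truth` (hourly
#'   DPM computed from truth labels), `record_start`, `record_end` (s),
#'   `config`.
#' @export
generate_deployment <- function(cfg) {
  validate_scenario_config(cfg)
  set.seed(cfg$seed)
  hi <- hourly_intensity(cfg)
  g <- stats::rgamma(nrow(hi), shape = cfg$overdispersion_k,
                     rate = cfg$overdispersion_k)
  counts <- stats::rpois(nrow(hi), hi$mu * g)

  enc_times <- unlist(lapply(which(counts > 0), function(i) {
    (hi$hour_index[i] - 1) * 3600 + sort(stats::runif(counts[i], 0, 3600))
  }), use.names = FALSE)
  enc_times <- sort(enc_times)
  if (length(enc_times) > 1) {
    keep <- c(TRUE, diff(enc_times) >= 60)
    # one pass is enough in practice; repeat until stable for safety
    while (!all(keep)) {
      enc_times <- enc_times[keep]
      keep <- if (length(enc_times) > 1) c(TRUE, diff(enc_times) >= 60) else TRUE
    }
  }

  record_end <- cfg$duration_days * 86400
  enc_times <- enc_times[enc_times < record_end - 30]
  is_social <- stats::runif(length(enc_times)) < cfg$social_fraction

  trains <- list(); truth <- list()
  for (i in seq_along(enc_times)) {
    if (is_social[i]) {
      seq_id <- sprintf("s%05d", i)
      bursts <- generate_social_sequence(cfg, id_prefix = seq_id)
      span <- max(vapply(bursts, function(b) b$times[length(b$times)], numeric(1)))
      # anchor the whole group inside the 15-s frame holding the encounter time
      f0 <- floor(enc_times[i] / cfg$frame_length) * cfg$frame_length
      slack <- cfg$frame_length - span
      start <- f0 + stats::runif(1, 0.1, max(0.11, slack - 0.1))
      for (b in bursts) {
        b$times <- b$times + start
        trains[[length(trains) + 1L]] <- b
        truth[[length(truth) + 1L]] <- data.frame(
          train_id = b$id, true_class = "social",
          true_pattern = attr(bursts, "pattern"), stringsAsFactors = FALSE)
      }
    } else {
      tid <- sprintf("f%05d", i)
      tr <- generate_foraging_train(cfg, id = tid)
      tr$times <- tr$times + enc_times[i]
      trains[[length(trains) + 1L]] <- tr
      truth[[length(truth) + 1L]] <- data.frame(
        train_id = tid, true_class = "foraging", true_pattern = "none",
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(train_id = character(0), true_class = character(0),
               true_pattern = character(0))

  labelled <- lapply(trains, function(tr) {
    tr$label <- if (truth$true_class[match(tr$id, truth$train_id)] == "social")
      "social" else "nonsocial"
    tr
  })
  dpm_truth <- if (length(labelled))
    aggregate_dpm(labelled, record_start = 0, record_end = record_end)
  else NULL

  structure(list(trains = trains, truth = truth, dpm_truth = dpm_truth,
                 record_start = 0, record_end = record_end, config = cfg),
            class = "deployment")
}

#' @export
print.deployment <- function(x, ...) {
  cat(sprintf("<deployment> %d days, %d trains (%d social, %d foraging)\n",
              x$config$duration_days, nrow(x$truth),
              sum(x$truth$true_class == "social"),
              sum(x$truth$true_class == "foraging")))
  invisible(x)
}

#' Write / read truth labels
#'
#' Plain-CSV round trip of per-train ground-truth class and pattern.
#'
#' @param truth `data.frame` with columns `train_id`, `true_class`,
#'   `true_pattern`.
#' @param path Output path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the
#'   `data.frame`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(c("train_id", "true_class", "true_pattern") %in% names(truth)))
  utils::write.csv(truth[, c("train_id", "true_class", "true_pattern")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, colClasses = "character")
}
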