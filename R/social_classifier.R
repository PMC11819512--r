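#' Social-marking criteria
#'
#' Operational version of the visual marking rules for social click trains.
#' A candidate is marked social only if it (a) shows no foraging structure —
#' neither a searching phase below 200 c/s nor a terminal feeding buzz /
#' upsweep; (b) is discrete, i.e. not part of a longer train; (c) repeats at
#' least twice within one 15-s frame; and (d) has a mean rate between 200
#' and 1,000 c/s. Any sign of foraging vetoes the social mark.
#'
#' "No visible searching phase" is operationalized as a tolerance: the train
#' fails (a) if more than `max_subthreshold_fraction` of its instantaneous
#' rates fall below `search_rate_threshold`, or any contiguous sub-threshold
#' run exceeds `buzz_trend_window` intervals. The buzz check is a robust
#' rising trend (Theil-Sen slope plus a sign test) over the terminal
#' `buzz_trend_window` rates, with the terminal rate above the train median.
#'
#' @param burst_rate_band Inclusive mean-rate band (c/s) for criterion (d).
#' @param search_rate_threshold Searching-phase rate boundary (c/s).
#' @param max_subthreshold_fraction Tolerated fraction of sub-threshold
#'   instantaneous rates before (a) fails.
#' @param buzz_trend_window Number of terminal inter-click intervals examined
#'   for the buzz trend (also the contiguous sub-threshold run limit).
#' @param min_repeats Minimum similar bursts per frame (criterion c).
#' @param repeat_window Repetition window (s); equals the frame length.
#' @param discreteness_gap Minimum silence (ms) before and after a burst for
#'   criterion (b).
#' @param similarity_min Minimum correlation between length-normalized rate
#'   profiles for two bursts to count as repeats.
#' @param pattern_smooth Moving-average window (profile points) used when
#'   counting rate-profile maxima for pattern labelling.
#' @return A `social_criteria` list.
#' @export
social_criteria <- function(burst_rate_band = c(200, 1000),
                            search_rate_threshold = 200,
                            max_subthreshold_fraction = 0.1,
                            buzz_trend_window = 10L,
                            min_repeats = 2L,
                            repeat_window = 15,
                            discreteness_gap = 150,
                            similarity_min = 0.7,
                            pattern_smooth = 5L) {
  if (burst_rate_band[1] > burst_rate_band[2]) stop("burst_rate_band must be ordered")
  if (min_repeats < 2) stop("min_repeats must be >= 2")
  structure(list(burst_rate_band = burst_rate_band,
                 search_rate_threshold = search_rate_threshold,
                 max_subthreshold_fraction = max_subthreshold_fraction,
                 buzz_trend_window = as.integer(buzz_trend_window),
                 min_repeats = as.integer(min_repeats),
                 repeat_window = repeat_window,
                 discreteness_gap = discreteness_gap,
                 similarity_min = similarity_min,
                 pattern_smooth = as.integer(pattern_smooth)),
            class = "social_criteria")
}

#' Criterion (a), part 1: visible searching phase
#'
#' @param train A `click_train` with >= 2 clicks.
#' @param criteria A [social_criteria()].
#' @return `TRUE` iff the sub-threshold rate fraction exceeds the tolerance
#'   or a contiguous sub-threshold run exceeds the trend window.
#' @export
has_searching_phase <- function(train, criteria = social_criteria()) {
  rates <- compute_rate_profile(train)$instantaneous_rates
  below <- rates < criteria$search_rate_threshold
  if (mean(below) > criteria$max_subthreshold_fraction) return(TRUE)
  if (!any(below)) return(FALSE)
  runs <- rle(below)
  max(runs$lengths[runs$values]) > criteria$buzz_trend_window
}

# Theil-Sen slope: median of all pairwise slopes
theil_sen_slope <- function(y) {
  n <- length(y)
  ij <- utils::combn(n, 2)
  stats::median((y[ij[2, ]] - y[ij[1, ]]) / (ij[2, ] - ij[1, ]))
}

#' Criterion (a), part 2: terminal feeding buzz / upsweep
#'
#' The terminal `buzz_trend_window` instantaneous rates must show a robustly
#' rising trend (positive Theil-Sen slope, one-sided sign test on successive
#' differences at p < 0.05) with the terminal rate (mean of the last three)
#' above the train's median rate. Trains shorter than the window are
#' evaluated as `FALSE` with a `"note"` attribute.
#'
#' @inheritParams has_searching_phase
#' @return Logical.
#' @export
ends_in_buzz <- function(train, criteria = social_criteria()) {
  rates <- compute_rate_profile(train)$instantaneous_rates
  w <- criteria$buzz_trend_window
  if (length(rates) < w) {
    out <- FALSE
    attr(out, "note") <- "train shorter than buzz trend window; buzz not assessable"
    return(out)
  }
  tail_r <- rates[(length(rates) - w + 1L):length(rates)]
  if (theil_sen_slope(tail_r) <= 0) return(FALSE)
  d <- diff(tail_r)
  d <- d[d != 0]
  if (!length(d)) return(FALSE)
  p <- stats::binom.test(sum(d > 0), length(d), alternative = "greater")$p.value
  terminal <- mean(tail_r[(w - 2):w])
  p < 0.05 && terminal > stats::median(rates)
}

#' Criterion (b): discreteness
#'
#' A burst is discrete if silence of at least `discreteness_gap` ms both
#' precedes its first click and follows its last click, relative to every
#' click of every other train in the record, and no foreign click falls
#' inside its span.
#'
#' @param train A `click_train`.
#' @param neighbors Other `click_train`s from the same site record.
#' @param criteria A [social_criteria()].
#' @return Logical.
#' @export
is_discrete <- function(train, neighbors, criteria = social_criteria()) {
  other <- unlist(lapply(neighbors, function(nb) {
    if (identical(nb$id, train$id)) NULL else nb$times
  }), use.names = FALSE)
  if (!length(other)) return(TRUE)
  gap_s <- criteria$discreteness_gap / 1000
  first <- train$times[1]; last <- train$times[length(train$times)]
  if (any(other >= first & other <= last)) return(FALSE)
  pre <- other[other < first]
  post <- other[other > last]
  (!length(pre) || first - max(pre) >= gap_s) &&
    (!length(post) || min(post) - last >= gap_s)
}

# rate profile on normalized time [0,1], reduced to n_points bin means
# (bin averaging suppresses per-interval jitter; empty bins interpolated)
normalized_profile <- function(train, n_points = 24L) {
  rp <- compute_rate_profile(train)
  t <- rp$midpoint_times
  if (length(t) < 2) return(rep(rp$instantaneous_rates[1], n_points))
  u <- (t - t[1]) / (t[length(t)] - t[1])
  bin <- pmin(floor(u * n_points) + 1L, n_points)
  means <- vapply(seq_len(n_points), function(b) {
    r <- rp$instantaneous_rates[bin == b]
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  if (anyNA(means)) {
    ok <- which(!is.na(means))
    means <- stats::approx(ok, means[ok], xout = seq_len(n_points), rule = 2)$y
  }
  means
}

# collapse a profile to its strictly alternating local extrema (incl. endpoints)
extrema_seq <- function(y) {
  y <- y[c(TRUE, diff(y) != 0)]
  if (length(y) < 3) return(y)
  d <- sign(diff(y))
  y[c(TRUE, d[-length(d)] != d[-1], TRUE)]
}

# number of interior local maxima with peak-to-valley persistence >= thr
count_prominent_maxima <- function(y, thr) {
  ext <- extrema_seq(y)
  repeat {
    n <- length(ext)
    if (n < 3) break
    dif <- abs(diff(ext))
    j <- which.min(dif)
    if (dif[j] >= thr) break
    ext <- ext[-c(j, j + 1L)]
  }
  n <- length(ext)
  if (n < 3) return(0L)
  sum(ext[2:(n - 1)] > ext[1:(n - 2)])
}

# are two bursts repeats of the same pattern?
bursts_similar <- function(a, b, criteria) {
  da <- diff(range(a$times)); db <- diff(range(b$times))
  ratio <- da / db
  if (ratio < 0.5 || ratio > 2) return(FALSE)
  pa <- normalized_profile(a); pb <- normalized_profile(b)
  if (stats::sd(pa) < 1e-9 || stats::sd(pb) < 1e-9) {
    # flat profiles: similar iff both flat and mean rates within 1.5x
    return(stats::sd(pa) < 1e-9 && stats::sd(pb) < 1e-9 &&
             max(mean(pa), mean(pb)) / min(mean(pa), mean(pb)) <= 1.5)
  }
  stats::cor(pa, pb) >= criteria$similarity_min
}

#' Criterion (c): repetition count within a frame
#'
#' Number of bursts (including the candidate itself) among the candidates of
#' one eligible frame whose rate profiles are mutually similar to the
#' candidate's: duration ratio within `[0.5, 2]` and correlation of
#' length-normalized profiles at least `similarity_min`.
#'
#' @param candidate A candidate `click_train`.
#' @param candidates_in_frame Candidate trains intersecting the same frame
#'   (may include `candidate`).
#' @param criteria A [social_criteria()].
#' @return Integer repeat count (>= 1).
#' @export
find_repeats <- function(candidate, candidates_in_frame,
                         criteria = social_criteria()) {
  others <- Filter(function(tr) !identical(tr$id, candidate$id), candidates_in_frame)
  1L + sum(vapply(others, function(tr) bursts_similar(candidate, tr, criteria),
                  logical(1)))
}

#' Criterion (d): mean rate in the social band
#'
#' @inheritParams has_searching_phase
#' @return `TRUE` iff mean rate lies in `burst_rate_band` (inclusive).
#' @export
in_rate_band <- function(train, criteria = social_criteria()) {
  mr <- compute_rate_profile(train)$mean_rate
  mr >= criteria$burst_rate_band[1] && mr <= criteria$burst_rate_band[2]
}

#' Classify candidate trains as social or non-social
#'
#' Applies criteria (a)-(d) to every candidate train. A train is social iff
#' it has no searching phase, does not end in a buzz, is discrete with
#' respect to all other trains in the record, repeats at least `min_repeats`
#' times in some eligible frame it intersects, and its mean rate is in band.
#' Any failure marks it non-social and records which criteria failed.
#' Social trains are then pattern-labelled (mushroom / wiggle).
#'
#' @param trains Candidate `click_train`s (from [candidate_view()]).
#' @param frames Eligible frame table (from [eligible_frames()]), whose
#'   membership is used to find per-frame candidate groups.
#' @param criteria A [social_criteria()].
#' @param neighbors All trains of the record for the discreteness check;
#'   defaults to `trains`.
#' @return `data.frame` with one row per train: `train_id`, `decision`
#'   (`"social"`/`"nonsocial"`), `failed_criteria` (comma-joined subset of
#'   `a_search, a_buzz, b_discrete, c_repeat, d_band`; empty for social),
#'   `pattern` (`"mushroom"`, `"wiggle"`, `"none"`).
#' @export
classify <- function(trains, frames, criteria = social_criteria(),
                     neighbors = trains) {
  if (!length(trains)) {
    return(data.frame(train_id = character(0), decision = character(0),
                      failed_criteria = character(0), pattern = character(0)))
  }
  mem <- attr(frames, "membership")
  ids <- vapply(trains, function(tr) tr$id, character(1))
  by_frame <- if (!is.null(mem) && nrow(mem)) split(mem$train_id, mem$frame_id)
              else list()

  # pooled sorted click times across the record for fast discreteness checks
  all_times <- sort(unlist(lapply(neighbors, function(tr) tr$times),
                           use.names = FALSE))
  gap_s <- criteria$discreteness_gap / 1000
  discrete_fast <- function(tr) {
    first <- tr$times[1]; last <- tr$times[length(tr$times)]
    lo <- findInterval(first - 1e-9, all_times)
    hi <- findInterval(last + 1e-9, all_times)
    if (hi - lo > n_clicks(tr)) return(FALSE)   # foreign click inside span
    (lo == 0 || first - all_times[lo] >= gap_s) &&
      (hi == length(all_times) || all_times[hi + 1] - last >= gap_s)
  }

  rows <- lapply(seq_along(trains), function(i) {
    tr <- trains[[i]]
    failed <- character(0)
    if (has_searching_phase(tr, criteria)) failed <- c(failed, "a_search")
    if (isTRUE(as.logical(ends_in_buzz(tr, criteria)))) failed <- c(failed, "a_buzz")
    if (!discrete_fast(tr)) failed <- c(failed, "b_discrete")

    # repeats: best count over the eligible frames this train intersects
    reps <- 1L
    for (grp in by_frame) {
      if (!(tr$id %in% grp)) next
      mates <- trains[ids %in% grp]
      reps <- max(reps, find_repeats(tr, mates, criteria))
    }
    if (reps < criteria$min_repeats) failed <- c(failed, "c_repeat")
    if (!in_rate_band(tr, criteria)) failed <- c(failed, "d_band")

    decision <- if (length(failed)) "nonsocial" else "social"
    data.frame(train_id = tr$id, decision = decision,
               failed_criteria = paste(failed, collapse = ";"),
               pattern = "none", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  soc <- which(out$decision == "social")
  if (length(soc)) {
    out$pattern[soc] <- vapply(trains[soc], function(tr) {
      tr$label <- "social"
      label_pattern(tr, criteria)
    }, character(1))
  }
  out
}

#' Label a social train's rate-profile pattern
#'
#' After reducing the train to its length-normalized, bin-averaged rate
#' profile and lightly smoothing it with a centred moving average, counts
#' the interior local maxima whose peak-to-valley persistence is at least a
#' quarter of the profile range: exactly one maximum is a "mushroom"
#' (unimodal rise-fall), two or more a "wiggle" (oscillating), zero "none".
#'
#' @param train A `click_train` already classified/labelled social.
#' @param criteria A [social_criteria()].
#' @return One of `"mushroom"`, `"wiggle"`, `"none"`.
#' @export
label_pattern <- function(train, criteria = social_criteria()) {
  if (!identical(train$label, "social"))
    stop("pattern labelling applies to social trains only")
  prof <- normalized_profile(train)
  k <- min(criteria$pattern_smooth, 3L)
  sm <- as.numeric(stats::filter(prof, rep(1 / k, k), sides = 2))
  sm <- sm[!is.na(sm)]
  if (length(sm) < 3) return("none")
  rng <- max(sm) - min(sm)
  if (rng < 1e-9) return("none")
  n_max <- count_prominent_maxima(sm, thr = 0.25 * rng)
  if (n_max == 1) "mushroom" else if (n_max >= 2) "wiggle" else "none"
}
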