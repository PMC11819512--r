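#' Construct a click train
#'
#' A click train is one vocal event: an ordered sequence of narrow-band
#' high-frequency (NBHF) echolocation or communication clicks. Times are
#' seconds since the start of the deployment record, so all trains from one
#' site share a clock; the absolute origin of that clock is carried as a
#' `POSIXct` attribute and is used for all wall-clock (minute, hour, month)
#' logic downstream.
#'
#' @param id Train identifier (coerced to character).
#' @param times Numeric vector of click times in seconds since record start;
#'   must be non-negative and strictly increasing.
#' @param freq Numeric vector of per-click centroid frequencies in kHz
#'   (recycled if length 1); must be positive.
#' @param site Site label.
#' @param origin `POSIXct` absolute time corresponding to `times == 0`.
#' @param label One of `"unlabelled"`, `"social"`, `"nonsocial"`.
#' @param pattern One of `"none"`, `"mushroom"`, `"wiggle"`.
#' @return An object of class `click_train`.
#' @export
click_train <- function(id, times, freq, site = "site1",
                        origin = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                        label = "unlabelled", pattern = "none") {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("click train must contain at least one click")
  if (any(times < 0)) stop("click times must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("unsorted train: click times must be strictly increasing")
  freq <- as.numeric(freq)
  if (length(freq) == 1L) freq <- rep(freq, length(times))
  if (length(freq) != length(times)) stop("freq must have length 1 or length(times)")
  if (any(freq <= 0)) stop("click frequencies must be positive")
  label <- match.arg(label, c("unlabelled", "social", "nonsocial"))
  pattern <- match.arg(pattern, c("none", "mushroom", "wiggle"))
  structure(
    list(id = as.character(id), times = times, freq = freq,
         site = as.character(site), origin = origin,
         label = label, pattern = pattern),
    class = "click_train"
  )
}

#' @export
print.click_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<click_train %s> site=%s  n=%d clicks  span=[%.3f, %.3f] s  label=%s\n",
              x$id, x$site, n, x$times[1], x$times[n], x$label))
  invisible(x)
}

#' Number of clicks in a train
#' @param train A `click_train`.
#' @return Integer click count.
#' @export
n_clicks <- function(train) length(train$times)

#' Inter-click intervals of a train
#'
#' Successive click-time differences in milliseconds. An ICI of 10 ms is the
#' conventional boundary between foraging-rate and social-rate clicking
#' (reciprocal rate 100 c/s).
#'
#' @param train A `click_train` with at least two clicks.
#' @return Numeric vector of length `n_clicks(train) - 1`, in ms, all > 0.
#' @export
ici_series <- function(train) {
  stopifnot(inherits(train, "click_train"))
  if (n_clicks(train) < 2L) stop("degenerate train: need at least 2 clicks for ICIs")
  d <- diff(train$times)
  if (any(d <= 0)) stop("unsorted train: click times must be strictly increasing")
  d * 1000
}

#' Click-rate profile of a train
#'
#' Instantaneous click rate is the reciprocal of each inter-click interval;
#' the mean rate is (n clicks - 1) / train duration, the quantity the F-POD
#' style "average click rate" filter operates on. The mean frequency is the
#' arithmetic mean of per-click centroid frequencies.
#'
#' @param train A `click_train` with at least two clicks.
#' @return A `rate_profile`: list with `midpoint_times` (s),
#'   `instantaneous_rates` (c/s), `mean_rate` (c/s), `mean_freq` (kHz),
#'   `duration` (s).
#' @export
compute_rate_profile <- function(train) {
  ici_s <- ici_series(train) / 1000
  times <- train$times
  duration <- times[length(times)] - times[1]
  structure(
    list(
      midpoint_times = (times[-length(times)] + times[-1]) / 2,
      instantaneous_rates = 1 / ici_s,
      mean_rate = (length(times) - 1L) / duration,
      mean_freq = mean(train$freq),
      duration = duration
    ),
    class = "rate_profile"
  )
}

#' Partition a record into fixed 15-second analysis frames
#'
#' Frames tile `[record_start, record_end)` on a fixed grid anchored at
#' `record_start` (not sliding, not clock-anchored). A train is a member of
#' every frame in which at least one of its clicks falls; frame click counts
#' include all clicks from all trains in the window.
#'
#' @param trains List of `click_train` objects on a common record clock.
#' @param record_start,record_end Record span in seconds; `record_end` must
#'   exceed `record_start`.
#' @param frame_length Frame length in seconds (default 15).
#' @return A `data.frame` with one row per frame: `frame_id`, `start_time`,
#'   `end_time`, `total_clicks`; train membership is attached as attribute
#'   `"membership"`, a `data.frame` with columns `frame_id`, `train_id`.
#' @export
frame_partition <- function(trains, record_start, record_end, frame_length = 15) {
  if (record_end <= record_start) stop("record_end must exceed record_start")
  n_frames <- ceiling((record_end - record_start) / frame_length)
  frames <- data.frame(
    frame_id = seq_len(n_frames),
    start_time = record_start + (seq_len(n_frames) - 1L) * frame_length
  )
  frames$end_time <- frames$start_time + frame_length

  idx_list <- lapply(trains, function(tr) {
    idx <- floor((tr$times - record_start) / frame_length) + 1L
    idx[idx >= 1L & idx <= n_frames]
  })
  frames$total_clicks <- tabulate(as.integer(unlist(idx_list, use.names = FALSE)),
                                  nbins = n_frames)
  member <- lapply(seq_along(trains), function(i) {
    u <- unique(idx_list[[i]])
    if (!length(u)) return(NULL)
    data.frame(frame_id = u, train_id = trains[[i]]$id, stringsAsFactors = FALSE)
  })
  member <- member[!vapply(member, is.null, logical(1))]
  membership <- if (length(member)) do.call(rbind, member) else
    data.frame(frame_id = integer(0), train_id = character(0))
  attr(frames, "membership") <- membership
  frames
}

#' Wall-clock minutes touched by a train
#'
#' A train's "home minutes" are every wall-clock minute containing at least
#' one of its clicks, the unit on which detection-positive minutes (DPM)
#' are counted.
#'
#' @param train A `click_train`.
#' @return `POSIXct` vector of distinct minute floors (same tz as origin).
#' @export
train_minutes <- function(train) {
  abs_t <- train$origin + train$times
  unique(as.POSIXct(trunc(abs_t, units = "mins")))
}
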