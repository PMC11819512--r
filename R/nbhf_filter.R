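#' Candidate filter configuration
#'
#' The detector-app style view settings applied before social marking: only
#' trains with a mean click rate of at least 100 c/s and mean centroid
#' frequency between 105 and 140 kHz are shown, and only 15-s frames holding
#' at least 256 clicks are scanned. All bounds are inclusive.
#'
#' @param min_mean_rate Minimum mean click rate (c/s).
#' @param freq_band Length-2 inclusive centroid-frequency band (kHz).
#' @param min_frame_clicks Minimum clicks per frame for frame eligibility.
#' @param frame_length Analysis frame length (s).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_mean_rate = 100, freq_band = c(105, 140),
                          min_frame_clicks = 256, frame_length = 15) {
  if (length(freq_band) != 2 || freq_band[1] > freq_band[2])
    stop("freq_band must be an ordered pair")
  if (min_mean_rate <= 0 || min_frame_clicks <= 0 || frame_length <= 0)
    stop("filter thresholds must be positive")
  structure(list(min_mean_rate = min_mean_rate, freq_band = freq_band,
                 min_frame_clicks = min_frame_clicks,
                 frame_length = frame_length),
            class = "filter_config")
}

#' Does a train pass the rate/frequency view filter?
#'
#' @param train A `click_train` with >= 2 clicks.
#' @param config A [filter_config()].
#' @return `TRUE` iff mean rate >= `min_mean_rate` and mean frequency lies
#'   inside `freq_band` (inclusive).
#' @export
train_passes_filter <- function(train, config = filter_config()) {
  rp <- compute_rate_profile(train)
  rp$mean_rate >= config$min_mean_rate &&
    rp$mean_freq >= config$freq_band[1] &&
    rp$mean_freq <= config$freq_band[2]
}

#' Frames eligible for social scanning
#'
#' Retains frames whose total click count (all trains, any class) reaches
#' `min_frame_clicks`; only these frames are scanned for social trains.
#'
#' @param frames Frame table from [frame_partition()].
#' @param config A [filter_config()].
#' @return Subset of `frames` (membership attribute filtered accordingly).
#' @export
eligible_frames <- function(frames, config = filter_config()) {
  keep <- frames$total_clicks >= config$min_frame_clicks
  out <- frames[keep, , drop = FALSE]
  mem <- attr(frames, "membership")
  if (!is.null(mem))
    attr(out, "membership") <- mem[mem$frame_id %in% out$frame_id, , drop = FALSE]
  out
}

#' Candidate trains for social classification
#'
#' Composition of the two filters: trains that pass the rate/frequency view
#' filter and intersect at least one eligible frame.
#'
#' @param trains List of `click_train`.
#' @param frames Frame table from [frame_partition()] over the same record.
#' @param config A [filter_config()].
#' @return List of candidate `click_train`s (a subset of `trains`).
#' @export
candidate_view <- function(trains, frames, config = filter_config()) {
  if (!length(trains)) return(list())
  elig <- eligible_frames(frames, config)
  mem <- attr(elig, "membership")
  in_elig <- vapply(trains, function(tr) tr$id %in% mem$train_id, logical(1))
  passes <- vapply(trains, function(tr) {
    n_clicks(tr) >= 2 && train_passes_filter(tr, config)
  }, logical(1))
  trains[in_elig & passes]
}
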