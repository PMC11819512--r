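#' Aggregate classified trains into hourly detection-positive minutes
#'
#' A wall-clock minute is social-positive if at least one social train has a
#' click in it, nonsocial-positive if at least one nonsocial train does, and
#' total-positive if either (union semantics: a minute positive for both
#' counts once in the total). Every hour covered by the record span gets a
#' row, zeros included; time outside the span is absent, not zero.
#'
#' @param trains List of `click_train`s whose `label` is `"social"` or
#'   `"nonsocial"` (e.g. set from a [classify()] decision).
#' @param record_start,record_end Record span in seconds on the trains'
#'   shared clock.
#' @param origin,site Clock origin (`POSIXct`) and site label; default to
#'   the first train's. Required when `trains` is empty.
#' @return `data.frame` with columns `site`, `date`, `hour` (0-23 local),
#'   `month`, `year`, `dpm_social`, `dpm_nonsocial`, `dpm_total`.
#' @export
aggregate_dpm <- function(trains, record_start, record_end,
                          origin = NULL, site = NULL) {
  if (length(trains)) {
    if (is.null(origin)) origin <- trains[[1]]$origin
    if (is.null(site)) site <- trains[[1]]$site
  } else if (is.null(origin) || is.null(site)) {
    stop("origin and site are required when no trains are supplied")
  }
  origin_s <- as.numeric(origin)

  soc_min <- numeric(0); non_min <- numeric(0)
  for (tr in trains) {
    if (!tr$label %in% c("social", "nonsocial"))
      stop("all trains must carry a social/nonsocial label before DPM aggregation")
    t0 <- tr$times[1]; t1 <- tr$times[length(tr$times)]
    if (t0 < record_start || t1 > record_end)
      stop("train ", tr$id, " falls outside the record span")
    mins <- unique(floor((origin_s + tr$times) / 60))
    if (tr$label == "social") soc_min <- c(soc_min, mins)
    else non_min <- c(non_min, mins)
  }
  soc_min <- unique(soc_min); non_min <- unique(non_min)

  first_hour <- floor((origin_s + record_start) / 3600)
  last_hour <- ceiling((origin_s + record_end) / 3600) - 1
  hours <- first_hour:last_hour
  hour_of <- function(mins) floor(mins / 60)

  tab <- function(mins) {
    cnt <- table(factor(hour_of(mins), levels = hours))
    as.integer(cnt)
  }
  dpm_social <- tab(soc_min)
  dpm_nonsocial <- tab(non_min)
  dpm_total <- tab(union(soc_min, non_min))

  hour_start <- as.POSIXct(hours * 3600, origin = "1970-01-01",
                           tz = attr(origin, "tzone") %||% "UTC")
  lt <- as.POSIXlt(hour_start)
  data.frame(
    site = site,
    date = format(hour_start, "%Y-%m-%d"),
    hour = lt$hour,
    month = lt$mon + 1L,
    year = lt$year + 1900L,
    dpm_social = dpm_social,
    dpm_nonsocial = dpm_nonsocial,
    dpm_total = dpm_total,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportion of social DPM by group
#'
#' Sums social and total DPM within levels of a grouping column and reports
#' the social percentage to one decimal, the headline statistic of the
#' analysis (e.g. 2,619 social of 49,811 total DPM gives 5.3%).
#'
#' @param dpm_rows Output of [aggregate_dpm()] (or any data.frame with
#'   `dpm_social`, `dpm_total` and the grouping column).
#' @param group_by One of `"month"`, `"hour"`, `"year"`, `"site"`, or
#'   `"overall"` for a single pooled row.
#' @return `data.frame` with `group`, `social_dpm`, `total_dpm`,
#'   `pct_social` (one decimal; `NA` where a group has zero total DPM).
#' @export
proportion_social <- function(dpm_rows, group_by = "overall") {
  if (!nrow(dpm_rows)) stop("no DPM rows to summarize")
  key <- if (identical(group_by, "overall")) rep("overall", nrow(dpm_rows))
         else dpm_rows[[group_by]]
  if (is.null(key)) stop("unknown grouping column: ", group_by)
  soc <- tapply(dpm_rows$dpm_social, key, sum)
  tot <- tapply(dpm_rows$dpm_total, key, sum)
  out <- data.frame(group = names(soc),
                    social_dpm = as.numeric(soc),
                    total_dpm = as.numeric(tot),
                    stringsAsFactors = FALSE)
  out$pct_social <- ifelse(out$total_dpm > 0,
                           round(100 * out$social_dpm / out$total_dpm, 1), NA)
  rownames(out) <- NULL
  out
}

#' Percent change between two totals
#'
#' @param value_from Baseline value (> 0).
#' @param value_to Later value.
#' @return `100 * (value_to - value_from) / value_from` (negative for a
#'   decline; e.g. annual DPM 15,006 to 6,948 gives -53.7).
#' @export
percent_change <- function(value_from, value_to) {
  if (value_from <= 0) stop("baseline value must be positive")
  100 * (value_to - value_from) / value_from
}

#' Directional inter-rater agreement on marked social minutes
#'
#' Given two analysts' sets of marked social-positive minutes keyed by hour,
#' reports the percentage of A's marked minutes also marked by B, and vice
#' versa (the quality-control comparison for triple-marked records).
#'
#' @param hours_a,hours_b `data.frame`s with columns `hour` (hour key) and
#'   `minute` (marked minute identifier), one row per marked minute. Both
#'   must cover the same set of hour keys.
#' @return Named numeric: `pct_a_in_b`, `pct_b_in_a` (percent; `NA` when a
#'   rater marked nothing).
#' @export
rater_agreement <- function(hours_a, hours_b) {
  if (!setequal(unique(hours_a$hour), unique(hours_b$hour)))
    stop("raters must cover the same hour keys")
  key <- function(d) paste(d$hour, d$minute)
  a <- unique(key(hours_a)); b <- unique(key(hours_b))
  c(pct_a_in_b = if (length(a)) 100 * sum(a %in% b) / length(a) else NA_real_,
    pct_b_in_a = if (length(b)) 100 * sum(b %in% a) / length(b) else NA_real_)
}

#' Precision and recall of social classification against truth
#'
#' Trains absent from the classification table (removed by the candidate
#' filters) count as non-social, so recall is measured against every
#' truth-social train in the deployment.
#'
#' @param classified Output of [classify()].
#' @param truth Truth table (`train_id`, `true_class`).
#' @return Named numeric: `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
classification_metrics <- function(classified, truth) {
  called_social <- classified$train_id[classified$decision == "social"]
  true_social <- truth$train_id[truth$true_class == "social"]
  tp <- sum(called_social %in% true_social)
  fp <- length(called_social) - tp
  fn <- length(true_social) - tp
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn)
}
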