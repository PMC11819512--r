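#' Shapiro-Wilk normality p-value
#'
#' Used to decide whether proportion data can be treated as parametric
#' before falling back to rank-based tests.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return The Shapiro-Wilk p-value.
#' @export
shapiro_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("constant sample: normality test undefined")
  stats::shapiro.test(x)$p.value
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H with a chi-square reference on k - 1 df, applied to
#' social-DPM proportions grouped by hour, month or year.
#'
#' @param values Numeric observations.
#' @param groups Grouping factor (>= 2 non-empty groups).
#' @param group_name Label for the tested factor.
#' @return A `kw_result` list: `H`, `df`, `p_value`, `group_factor`.
#' @export
kruskal_wallis <- function(values, groups, group_name = deparse(substitute(groups))) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("every group must contain observations")
  kt <- stats::kruskal.test(values, groups)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, group_factor = group_name),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on %s: H = %.4f, df = %d, p = %.4g\n",
              x$group_factor, x$H, x$df, x$p_value))
  invisible(x)
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics from pooled midranks with tie correction,
#' Bonferroni-adjusted over all pairs within the tested factor
#' (p_adj = min(1, m * p_raw), m = number of pairs).
#'
#' @inheritParams kruskal_wallis
#' @return A `dunn_result` data.frame: `group1`, `group2`, `z`, `p_raw`,
#'   `p_adj`.
#' @export
dunn_bonferroni <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("every group must contain observations")
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_c <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  z <- vapply(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    (rbar[g1] - rbar[g2]) /
      sqrt((N * (N + 1) / 12 - tie_c) * (1 / n[g1] + 1 / n[g2]))
  }, numeric(1))
  p_raw <- 2 * stats::pnorm(-abs(z))
  structure(data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                       z = z, p_raw = p_raw,
                       p_adj = pmin(1, m * p_raw),
                       stringsAsFactors = FALSE),
            class = c("dunn_result", "data.frame"))
}

#' Variance-inflation-factor screen
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing covariate j on the others;
#' covariates with VIF above the cutoff (default 5) are flagged as collinear.
#' Singular relationships are reported as infinite VIF.
#'
#' @param covariates `data.frame` of numeric covariates (>= 2 columns, more
#'   rows than columns).
#' @param cutoff Flagging threshold.
#' @return `data.frame` with `covariate`, `vif`, `flagged`.
#' @export
vif_screen <- function(covariates, cutoff = 5) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2) stop("need at least 2 covariates")
  if (nrow(covariates) <= ncol(covariates)) stop("need more observations than covariates")
  vifs <- vapply(seq_along(covariates), function(j) {
    fit <- stats::lm(covariates[[j]] ~ ., data = covariates[-j])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = names(covariates), vif = vifs,
             flagged = vifs > cutoff, stringsAsFactors = FALSE)
}

#' Lag-1 autocorrelation and AR1 decision
#'
#' @param residuals Numeric series, n >= 10, non-constant.
#' @param threshold Absolute autocorrelation above which an AR1 residual
#'   structure is deemed necessary (default 0.2).
#' @return List with `rho` (lag-1 autocorrelation) and `needs_ar1`.
#' @export
acf_lag1 <- function(residuals, threshold = 0.2) {
  if (length(residuals) < 10) stop("need at least 10 observations")
  if (stats::sd(residuals) == 0) stop("constant series: autocorrelation undefined")
  rho <- stats::acf(residuals, lag.max = 1, plot = FALSE)$acf[2]
  list(rho = rho, needs_ar1 = abs(rho) > threshold)
}

#' Negative-binomial GAM specification
#'
#' Cyclic cubic smooths of hour (period 24) and month (period 12) plus a
#' year factor, negative-binomial family with log link, smoothing parameters
#' by (fast) REML, and an optional AR1 working residual structure triggered
#' when the lag-1 residual autocorrelation exceeds 0.2.
#'
#' @param response `"dpm_social"` or `"dpm_nonsocial"`.
#' @param terms Subset of `c("hour", "month", "year")` to include.
#' @param k_hour,k_month Cyclic spline basis dimensions.
#' @param ar1 `"auto"` (refit with AR1 when the residual lag-1
#'   autocorrelation exceeds `ar1_threshold`), `TRUE`, or `FALSE`.
#' @param ar1_threshold ACF threshold for the auto decision.
#' @return A `gam_spec` list.
#' @export
gam_spec <- function(response = c("dpm_social", "dpm_nonsocial"),
                     terms = c("hour", "month", "year"),
                     k_hour = 8, k_month = 6,
                     ar1 = "auto", ar1_threshold = 0.2) {
  response <- match.arg(response)
  terms <- if (length(terms))
    match.arg(terms, c("hour", "month", "year"), several.ok = TRUE)
  else character(0)
  structure(list(response = response, terms = terms, k_hour = k_hour,
                 k_month = k_month, ar1 = ar1, ar1_threshold = ar1_threshold),
            class = "gam_spec")
}

gam_formula <- function(spec, data) {
  parts <- character(0)
  if ("hour" %in% spec$terms)
    parts <- c(parts, sprintf("s(hour, bs = 'cc', k = %d)", spec$k_hour))
  if ("month" %in% spec$terms)
    parts <- c(parts, sprintf("s(month, bs = 'cc', k = %d)", spec$k_month))
  if ("year" %in% spec$terms && length(unique(data$year)) > 1)
    parts <- c(parts, "year_f")
  if (!length(parts)) parts <- "1"
  stats::as.formula(paste("count ~", paste(parts, collapse = " + ")))
}

#' Fit a negative-binomial GAM to hourly DPM counts
#'
#' Penalized-regression-spline negative-binomial model of an hourly DPM
#' series with cyclic hour and month smooths (knots wrapping 24 -> 0 and
#' December -> January) and a year factor, fitted with [mgcv::bam()] by fast
#' REML. If the working-residual lag-1 autocorrelation exceeds the
#' threshold (or `ar1 = TRUE`), the model is refitted with `bam`'s AR1
#' structure at that estimated rho.
#'
#' @param dpm_rows Hourly DPM table from [aggregate_dpm()], in time order.
#' @param spec A [gam_spec()].
#' @return A `gam_fit_result`: `fit` (the mgcv object), `aic`, `adj_r2`,
#'   `dev_expl`, `theta` (NB size), `ar1_rho` (0 when no AR1 used),
#'   `s_table`, `p_table`, `term_p` (named p-values per model term),
#'   `spec`, `fitted`.
#' @export
fit_nb_gam <- function(dpm_rows, spec = gam_spec()) {
  data <- dpm_rows
  data$count <- data[[spec$response]]
  if (is.null(data$count)) stop("response column not found: ", spec$response)
  data$year_f <- factor(data$year)
  n_par <- 2 + ("hour" %in% spec$terms) * (spec$k_hour - 1) +
    ("month" %in% spec$terms) * (spec$k_month - 1) +
    ("year" %in% spec$terms) * max(0, length(unique(data$year)) - 1)
  if (nrow(data) < 10 * n_par)
    warning("fewer than 10 observations per parameter; fit may be unstable")

  knots <- list()
  if ("hour" %in% spec$terms) knots$hour <- c(0, 24)
  if ("month" %in% spec$terms) knots$month <- c(0.5, 12.5)

  fml <- gam_formula(spec, data)
  fit <- try(mgcv::bam(fml, data = data, family = mgcv::nb(),
                       knots = knots, method = "fREML", discrete = TRUE),
             silent = TRUE)
  if (inherits(fit, "try-error") || !fit$converged)
    stop("negative-binomial GAM failed to converge: ",
         if (inherits(fit, "try-error")) attr(fit, "condition")$message else "")

  rho <- 0
  used_ar1 <- FALSE
  if (!identical(spec$ar1, FALSE)) {
    ac <- acf_lag1(stats::residuals(fit, type = "pearson"),
                   threshold = spec$ar1_threshold)
    if (isTRUE(spec$ar1) || ac$needs_ar1) {
      rho <- ac$rho
      fit <- mgcv::bam(fml, data = data, family = mgcv::nb(),
                       knots = knots, method = "fREML", discrete = TRUE,
                       rho = rho, AR.start = c(TRUE, rep(FALSE, nrow(data) - 1)))
      used_ar1 <- TRUE
    }
  }

  sm <- summary(fit)
  term_p <- c(
    if (nrow(sm$s.table)) stats::setNames(sm$s.table[, "p-value"],
                                          rownames(sm$s.table)),
    if (!is.null(sm$pTerms.table) && nrow(sm$pTerms.table))
      stats::setNames(sm$pTerms.table[, "p-value"], rownames(sm$pTerms.table))
  )
  structure(list(fit = fit, aic = stats::AIC(fit), adj_r2 = sm$r.sq,
                 dev_expl = sm$dev.expl,
                 theta = fit$family$getTheta(TRUE),
                 ar1_rho = if (used_ar1) rho else 0,
                 s_table = sm$s.table, p_table = sm$p.table,
                 term_p = term_p, spec = spec,
                 fitted = stats::fitted(fit)),
            class = "gam_fit_result")
}

#' @export
print.gam_fit_result <- function(x, ...) {
  cat(sprintf("NB-GAM for %s: AIC = %.1f, adj R2 = %.3f, dev expl = %.1f%%, theta = %.2f, AR1 rho = %.2f\n",
              x$spec$response, x$aic, x$adj_r2, 100 * x$dev_expl, x$theta,
              x$ar1_rho))
  if (length(x$term_p)) {
    cat("term p-values:\n")
    print(signif(x$term_p, 3))
  }
  invisible(x)
}

#' Location of a fitted smooth's maximum
#'
#' Evaluates one fitted cyclic smooth on a fine grid (other covariates held
#' fixed; they do not affect the term's own contribution) and returns the
#' covariate value at which it peaks.
#'
#' @param gfr A `gam_fit_result` containing the smooth.
#' @param term `"hour"` or `"month"`.
#' @return Grid value of the smooth's maximum (hour in [0, 24), month in
#'   [1, 12]).
#' @export
smooth_peak <- function(gfr, term = c("hour", "month")) {
  term <- match.arg(term)
  data <- gfr$fit$model
  if (is.null(data[[term]])) stop("no fitted smooth for term: ", term)
  obs <- range(data[[term]])
  grid <- if (term == "hour") seq(obs[1], obs[2], by = 0.1)
          else seq(obs[1], obs[2], by = 0.05)
  nd <- data.frame(grid)
  names(nd) <- term
  for (v in setdiff(names(data), c(term, "count"))) {
    nd[[v]] <- if (is.factor(data[[v]])) data[[v]][1] else stats::median(data[[v]])
  }
  tm <- stats::predict(gfr$fit, newdata = nd, type = "terms")
  col <- grep(paste0("s\\(", term, "\\)"), colnames(tm))
  if (!length(col)) stop("no fitted smooth for term: ", term)
  grid[which.max(tm[, col[1]])]
}

#' Backward term selection for the DPM GAM
#'
#' Sequentially removes the least significant term with p > 0.05 (smooths
#' and parametric terms alike), refitting after each removal, until every
#' retained term is significant. Reports the AIC trajectory. If every term
#' is removed an intercept-only model is returned with a warning.
#'
#' @param dpm_rows Hourly DPM table.
#' @param spec Starting [gam_spec()] (must contain at least one term).
#' @param alpha Removal threshold.
#' @return List: `fit` (final `gam_fit_result`), `spec` (final spec),
#'   `dropped` (terms removed, in order), `aic_trajectory`.
#' @export
backward_select <- function(dpm_rows, spec = gam_spec(), alpha = 0.05) {
  if (!length(spec$terms)) stop("no candidate terms to select over")
  term_key <- function(nm) {
    if (grepl("s\\(hour\\)", nm)) "hour"
    else if (grepl("s\\(month\\)", nm)) "month"
    else "year"
  }
  cur <- spec
  fit <- fit_nb_gam(dpm_rows, cur)
  aic_path <- fit$aic
  dropped <- character(0)
  repeat {
    p <- fit$term_p
    worst <- which.max(p)
    if (!length(p) || p[worst] <= alpha) break
    drop_term <- term_key(names(p)[worst])
    cur$terms <- setdiff(cur$terms, drop_term)
    dropped <- c(dropped, drop_term)
    if (!length(cur$terms)) {
      warning("all terms removed; returning intercept-only model")
    }
    fit <- fit_nb_gam(dpm_rows, cur)
    aic_path <- c(aic_path, fit$aic)
    if (!length(cur$terms)) break
  }
  list(fit = fit, spec = cur, dropped = dropped, aic_trajectory = aic_path)
}
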