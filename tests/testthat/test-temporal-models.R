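test_that("Shapiro-Wilk wrapper behaves on clean and degenerate input", {
  set.seed(51)
  expect_gt(shapiro_normality(rnorm(500)), 0.05)
  expect_error(shapiro_normality(rep(1, 20)), "constant")
  expect_error(shapiro_normality(c(1, 2)), "3 <= n")
  # heavy-tailed samples are flagged essentially always
  rejections <- sum(vapply(1:200, function(i) {
    set.seed(i)
    shapiro_normality(rcauchy(500)) < 0.05
  }, logical(1)))
  expect_gte(rejections, 198)
})

test_that("Kruskal-Wallis matches the brute-force rank oracle on toy data", {
  # identical groups: H = 0, p = 1
  kw <- kruskal_wallis(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 0)
  expect_equal(kw$p_value, 1)

  # values 1..9 split consecutively into 3 groups
  v <- 1:9; g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  or <- oracle_kw(v, g)
  expect_equal(kw$H, or$H)
  expect_equal(kw$p_value, or$p)
  expect_equal(kw$df, 2)

  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 groups")
})

test_that("Dunn-Bonferroni matches hand-computed ranks and never shrinks p", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- dunn_bonferroni(v, g)
  or <- oracle_dunn(v, g)
  expect_equal(d$z, or$z, tolerance = 1e-12)
  expect_equal(d$p_adj, or$p_adj, tolerance = 1e-12)
  expect_true(all(d$p_adj >= d$p_raw))

  # two groups: a single pair, so adjusted equals raw
  d2 <- dunn_bonferroni(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(d2$p_adj, d2$p_raw)
  expect_error(dunn_bonferroni(1:3, rep("a", 3)), "2 groups")
})

test_that("VIF screen matches its closed form", {
  set.seed(61)
  n <- 200
  x1 <- rnorm(n)
  x2r <- residuals(lm(rnorm(n) ~ x1))
  # construct x2 with sample correlation exactly 0.9 to x1
  x1s <- scale(x1)[, 1]; x2s <- scale(x2r)[, 1]
  x2 <- 0.9 * x1s + sqrt(1 - 0.81) * x2s
  v <- vif_screen(data.frame(a = x1s, b = x2))
  expect_equal(v$vif[v$covariate == "a"], 1 / (1 - 0.81), tolerance = 1e-8)
  expect_true(all(v$flagged))

  # mutually orthogonal centred covariates: all VIF exactly 1
  o1 <- rnorm(n)
  o2 <- residuals(lm(rnorm(n) ~ o1))
  o3 <- residuals(lm(rnorm(n) ~ o1 + o2))
  vo <- vif_screen(data.frame(o1, o2, o3))
  expect_true(all(vo$vif < 1 + 1e-10))

  # duplicated covariate: infinite, flagged
  vd <- vif_screen(data.frame(a = x1, b = x1))
  expect_true(all(is.infinite(vd$vif)))
  expect_true(all(vd$flagged))

  expect_error(vif_screen(data.frame(a = 1:10)), "at least 2")
})

test_that("VIF screen agrees with car::vif on a joint model", {
  skip_if_not_installed("car")
  set.seed(62)
  X <- data.frame(a = rnorm(100), b = rnorm(100))
  X$c <- 0.7 * X$a + 0.5 * X$b + rnorm(100, sd = 0.4)
  y <- rnorm(100)
  ours <- vif_screen(X)
  theirs <- car::vif(lm(y ~ a + b + c, data = X))
  expect_equal(ours$vif, unname(theirs[ours$covariate]), tolerance = 1e-8)
})

test_that("lag-1 autocorrelation estimation and AR1 flagging", {
  set.seed(71)
  wn <- rnorm(10000)
  ac <- acf_lag1(wn)
  expect_lt(abs(ac$rho), 0.05)
  expect_false(ac$needs_ar1)

  ar <- as.numeric(arima.sim(list(ar = 0.6), 10000))
  ac <- acf_lag1(ar)
  expect_equal(ac$rho, 0.6, tolerance = 0.05)
  expect_true(ac$needs_ar1)

  expect_error(acf_lag1(rep(2, 100)), "constant")
  expect_error(acf_lag1(rnorm(5)), "at least 10")
})

sim_dpm_counts <- function(n, theta = 2, hour_amp = 0.6, month_amp = 0.4,
                           seed = 1) {
  set.seed(seed)
  hour <- (seq_len(n) - 1) %% 24
  month <- ((seq_len(n) - 1) %/% 24) %% 12 + 1
  mu <- exp(1 + hour_amp * cos(2 * pi * (hour - 23) / 24) +
              month_amp * sin(2 * pi * month / 12))
  data.frame(hour = hour, month = month, year = 2020,
             dpm_social = rnbinom(n, size = theta, mu = mu),
             dpm_nonsocial = rpois(n, mu), dpm_total = 0)
}

test_that("the cyclic hour smooth is continuous across midnight", {
  df <- sim_dpm_counts(2000, seed = 81)
  fit <- fit_nb_gam(df, gam_spec("dpm_social", terms = c("hour", "month")))
  nd <- data.frame(hour = c(0, 24), month = 6)
  tm <- predict(fit$fit, newdata = nd, type = "terms")
  col <- grep("s\\(hour\\)", colnames(tm))
  expect_equal(tm[1, col], tm[2, col], tolerance = 1e-10)
})

test_that("NB fit approaches the Poisson fit on Poisson data", {
  df <- sim_dpm_counts(2000, seed = 82)
  df$dpm_social <- df$dpm_nonsocial  # Poisson response
  nb <- fit_nb_gam(df, gam_spec("dpm_social", terms = c("hour", "month"),
                                ar1 = FALSE))
  pois <- mgcv::bam(dpm_social ~ s(hour, bs = "cc", k = 8) +
                      s(month, bs = "cc", k = 6),
                    data = df, family = poisson(),
                    knots = list(hour = c(0, 24), month = c(0.5, 12.5)),
                    method = "fREML", discrete = TRUE)
  expect_gt(nb$theta, 20)  # dispersion pushed towards the Poisson limit
  expect_equal(deviance(nb$fit) / deviance(pois), 1, tolerance = 0.05)
  expect_equal(as.numeric(fitted(nb$fit)), as.numeric(fitted(pois)),
               tolerance = 0.01)
})

test_that("NB dispersion and smooth peaks are recovered from simulated counts", {
  df <- sim_dpm_counts(4000, theta = 2, seed = 83)
  fit <- fit_nb_gam(df, gam_spec("dpm_social", terms = c("hour", "month")))
  expect_lt(abs(fit$theta - 2) / 2, 0.5)
  peak <- smooth_peak(fit, "hour")
  expect_lte(min(abs(peak - 23), 24 - abs(peak - 23)), 1)
})

test_that("null smooth terms are usually non-significant on flat data", {
  hits <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 1200
    df <- data.frame(hour = (seq_len(n) - 1) %% 24,
                     month = ((seq_len(n) - 1) %/% 24) %% 12 + 1,
                     year = 2020,
                     dpm_social = rpois(n, 3), dpm_nonsocial = 0, dpm_total = 0)
    fit <- fit_nb_gam(df, gam_spec("dpm_social", terms = c("hour", "month"),
                                   ar1 = FALSE))
    if (all(fit$term_p > 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 17)  # ~alpha = 0.05 per term
})

test_that("backward selection drops flat terms and keeps real ones", {
  # month has no true effect: it should usually be removed, hour retained
  dropped_month <- 0; kept_hour <- 0
  for (s in 1:10) {
    df <- sim_dpm_counts(1500, month_amp = 0, seed = 900 + s)
    sel <- backward_select(df, gam_spec("dpm_social", terms = c("hour", "month"),
                                        ar1 = FALSE))
    dropped_month <- dropped_month + ("month" %in% sel$dropped)
    kept_hour <- kept_hour + ("hour" %in% sel$spec$terms)
    expect_equal(length(sel$aic_trajectory), length(sel$dropped) + 1)
  }
  expect_gte(dropped_month, 8)
  expect_equal(kept_hour, 10)

  # an all-significant model is returned unchanged
  df2 <- sim_dpm_counts(2000, seed = 92)
  sel2 <- backward_select(df2, gam_spec("dpm_social", terms = c("hour", "month"),
                                        ar1 = FALSE))
  expect_equal(sel2$dropped, character(0))

  expect_error(backward_select(df2, gam_spec("dpm_social", terms = character(0))),
               "no candidate terms")
})

test_that("AR1 refit preserves coefficient signs under moderate correlation", {
  set.seed(95)
  n <- 2000
  hour <- (seq_len(n) - 1) %% 24
  eps <- as.numeric(arima.sim(list(ar = 0.6), n, sd = 0.4))
  df <- data.frame(hour = hour, month = rep(1:12, length.out = n), year = 2020,
                   dpm_social = rpois(n, exp(1 + 0.5 * cos(2 * pi * (hour - 23) / 24) + eps)),
                   dpm_nonsocial = 0, dpm_total = 0)
  plain <- fit_nb_gam(df, gam_spec("dpm_social", terms = "hour", ar1 = FALSE))
  ar1 <- fit_nb_gam(df, gam_spec("dpm_social", terms = "hour", ar1 = TRUE))
  expect_gt(ar1$ar1_rho, 0.2)
  expect_lte(min(abs(smooth_peak(ar1, "hour") - 23),
                 24 - abs(smooth_peak(ar1, "hour") - 23)), 2)
  expect_equal(sign(coef(plain$fit)[1]), sign(coef(ar1$fit)[1]))
})
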