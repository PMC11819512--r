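# Independent brute-force oracles for the rank-based tests.
# Midranks are computed by counting (not base rank()), and the H statistic
# uses the between/within sum-of-squares form, so these share no code path
# with the package implementations.

counting_midranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# tie-corrected Kruskal-Wallis H as (N-1) * SSbetween / SStotal on midranks
oracle_kw <- function(values, groups) {
  groups <- as.factor(groups)
  r <- counting_midranks(values)
  rbar <- mean(r)
  ssb <- 0
  for (g in levels(groups)) {
    rg <- r[groups == g]
    ssb <- ssb + length(rg) * (mean(rg) - rbar)^2
  }
  sst <- sum((r - rbar)^2)
  H <- (length(values) - 1) * ssb / sst
  list(H = H, df = nlevels(groups) - 1,
       p = stats::pchisq(H, nlevels(groups) - 1, lower.tail = FALSE))
}

# Dunn z from counting midranks, tie term from value multiplicities counted
# with a loop over unique values
oracle_dunn <- function(values, groups) {
  groups <- as.factor(groups)
  r <- counting_midranks(values)
  N <- length(values)
  tie_sum <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie_sum <- tie_sum + (t^3 - t)
  }
  denom_base <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p_adj = NA_real_)
  for (j in seq_len(m)) {
    r1 <- r[groups == pairs[1, j]]; r2 <- r[groups == pairs[2, j]]
    z <- (mean(r1) - mean(r2)) /
      sqrt(denom_base * (1 / length(r1) + 1 / length(r2)))
    out$z[j] <- z
    out$p_adj[j] <- min(1, m * 2 * stats::pnorm(-abs(z)))
  }
  out
}

# every assignment of n items to k labelled non-empty groups, first item in
# group 1 (canonical form, since group labels are exchangeable)
enumerate_groupings <- function(n, k) {
  grids <- rep(list(seq_len(k)), n - 1)
  g <- as.matrix(expand.grid(grids))
  g <- cbind(1L, g)
  g[apply(g, 1, function(row) length(unique(row)) == k), , drop = FALSE]
}
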