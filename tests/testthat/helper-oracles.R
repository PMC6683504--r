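# Independent brute-force oracles, deliberately naive implementations used
# only to cross-check the package's statistics on small instances.

km_oracle <- function(times, events) {
  grid <- sort(unique(times))
  surv <- numeric(length(grid))
  s <- 1
  for (k in seq_along(grid)) {
    t <- grid[k]
    n_at_risk <- sum(times >= t)
    d <- sum(times == t & events)
    if (n_at_risk > 0 && d > 0) s <- s * (1 - d / n_at_risk)
    surv[k] <- s
  }
  data.frame(time = grid, survival = surv)
}

logrank_oracle <- function(times, events, group) {
  group <- as.integer(factor(group))
  stopifnot(length(unique(group)) == 2)
  ts <- sort(unique(times[events]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & group == 1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # step-up: running minimum from the largest rank down
  for (i in (m - 1):1) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  support <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(statistic = tt,
       p = 2 * stats::pt(abs(tt), nx + ny - 2, lower.tail = FALSE))
}
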