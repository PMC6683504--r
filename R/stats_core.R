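#' Kaplan-Meier product-limit survival curve
#'
#' Right-censored product-limit estimate on the event-time grid, via
#' \code{survival::survfit}.
#'
#' @param times non-negative follow-up times.
#' @param events logical (or 0/1) event indicators.
#' @return object of class `km_curve`: data.frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
kaplan_meier <- function(times, events) {
  check_numeric(times, "times", lower = 0)
  events <- as.logical(events)
  stopifnot(length(times) == length(events), length(times) >= 1L)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival time from a curve
#'
#' Smallest event time at which the survival probability drops to 0.5 or
#' below; NA when the curve never reaches 0.5.
#'
#' @param curve a `km_curve`.
#' @return numeric scalar (possibly NA).
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  i <- which(curve$survival <= 0.5)
  if (length(i) == 0L) NA_real_ else curve$time[min(i)]
}

#' Log-rank test
#'
#' Standard log-rank chi-square comparing two or more survival curves
#' (observed minus expected events over shared event times), via
#' \code{survival::survdiff}. With no events at all the statistic is 0 and
#' p = 1 by convention.
#'
#' @param times,events as in [kaplan_meier()].
#' @param groups group labels; at least two non-empty groups.
#' @return list of class `logrank_result`: `chisq`, `df`, `p`, `n_groups`,
#'   `group_n`.
#' @export
logrank_test <- function(times, events, groups) {
  check_numeric(times, "times", lower = 0)
  events <- as.logical(events)
  groups <- factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) {
    rd_stop("log-rank requires at least 2 non-empty groups (df = groups - 1)",
            "rd_df_error")
  }
  if (sum(events) == 0L) {
    res <- list(chisq = 0, df = k - 1L, p = 1,
                n_groups = k, group_n = table(groups))
    class(res) <- "logrank_result"
    return(res)
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- k - 1L
  res <- list(chisq = unname(sd$chisq), df = df,
              p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
              n_groups = k, group_n = table(groups))
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.4g on %d df, p = %.4g (groups: %s)\n",
              x$chisq, x$df, x$p, paste(x$group_n, collapse = "/")))
  invisible(x)
}

#' Proportional-hazards hazard ratio
#'
#' Cox proportional-hazards estimate of the hazard ratio for a binary
#' exposure, optionally adjusted for covariates, with a 95\% Wald confidence
#' interval. Ties are handled with the Efron approximation (month-resolution
#' follow-up ties often). A group with no events makes the estimate
#' non-identifiable: a warning is raised and `unbounded` is set.
#'
#' @param times,events as in [kaplan_meier()].
#' @param group binary exposure (logical, 0/1, or two-level factor).
#' @param covariates optional data.frame of adjustment columns (continuous or
#'   categorical).
#' @return list of class `hazard_ratio_result`: `hr`, `ci_lower`, `ci_upper`,
#'   `p`, `n`, `n_exposed`, `events_by_group`, `unbounded`, and `covariates`
#'   (coefficient table) when adjusted.
#' @export
hazard_ratio <- function(times, events, group, covariates = NULL) {
  check_numeric(times, "times", lower = 0)
  events <- as.logical(events)
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(as.logical(group))
  if (length(unique(g)) != 2L) {
    rd_stop("`group` must be a binary exposure with both levels present",
            "rd_value_error")
  }
  ev_by <- tapply(events, g, sum)
  unbounded <- any(ev_by == 0)
  if (unbounded) {
    warning("a group has no events; hazard ratio is not identifiable (CI unbounded)")
  }
  dat <- data.frame(.time = times, .event = events, .group = g)
  rhs <- ".group"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(times))
    dat <- cbind(dat, covariates)
    rhs <- paste(c(".group", names(covariates)), collapse = " + ")
  }
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::coxph(form, data = dat, ties = "efron")
  sm <- summary(fit)
  co <- sm$coefficients
  i <- grep("^\\.group", rownames(co))[1]
  hr <- unname(co[i, "exp(coef)"])
  se <- unname(co[i, "se(coef)"])
  ci <- exp(unname(co[i, "coef"]) + c(-1, 1) * stats::qnorm(0.975) * se)
  res <- list(hr = hr, ci_lower = ci[1], ci_upper = if (unbounded) Inf else ci[2],
              p = unname(co[i, "Pr(>|z|)"]),
              n = length(times), n_exposed = sum(g == 1L),
              events_by_group = ev_by, unbounded = unbounded,
              covariates = if (!is.null(covariates)) co[-i, , drop = FALSE] else NULL)
  class(res) <- "hazard_ratio_result"
  res
}

#' @export
print.hazard_ratio_result <- function(x, ...) {
  cat(sprintf("HR = %.3g (95%% CI %.3g-%.3g), p = %.3g; n = %d (%d exposed)%s\n",
              x$hr, x$ci_lower, x$ci_upper, x$p, x$n, x$n_exposed,
              if (x$unbounded) " [non-identifiable: a group has no events]" else ""))
  invisible(x)
}

#' Two-tailed Student's t test
#'
#' Pooled-variance two-sample (or paired one-sample) Student's t test. When
#' the data are constant with equal means the statistic is 0 and p = 1 by
#' convention.
#'
#' @param x,y numeric vectors; equal lengths required when `paired`.
#' @param paired logical.
#' @return list with `statistic`, `p`, `df`, `mean_diff`.
#' @export
t_test2 <- function(x, y, paired = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (paired && length(x) != length(y)) {
    rd_stop("paired t test requires equal lengths", "rd_value_error")
  }
  md <- if (paired) mean(x - y) else mean(x) - mean(y)
  res <- tryCatch(
    stats::t.test(x, y, paired = paired, var.equal = TRUE),
    error = function(e) NULL)
  if (!is.null(res) && !is.finite(res$statistic)) res <- NULL
  if (is.null(res)) {
    # degenerate (constant) data
    if (isTRUE(all.equal(md, 0)) || md == 0) {
      return(list(statistic = 0, p = 1,
                  df = if (paired) length(x) - 1 else length(x) + length(y) - 2,
                  mean_diff = md))
    }
    return(list(statistic = sign(md) * Inf, p = 0,
                df = if (paired) length(x) - 1 else length(x) + length(y) - 2,
                mean_diff = md))
  }
  list(statistic = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), mean_diff = md)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA F test across two or more groups.
#' All-identical data returns F = 0, p = 1 by convention.
#'
#' @param groups list of numeric vectors, one per group.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- lengths(groups)
  if (any(n < 1L) || sum(n) <= length(groups)) {
    rd_stop("one_way_anova needs every group non-empty and total n > number of groups",
            "rd_value_error")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  df1 <- length(groups) - 1L
  df2 <- sum(n) - length(groups)
  if (stats::var(values) == 0) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  }
  res <- tryCatch(
    stats::oneway.test(values ~ g, var.equal = TRUE),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic)) {
    # zero within-group variance with distinct means
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  list(F = unname(res$statistic), p = res$p.value, df1 = df1, df2 = df2)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\] (NA allowed).
#' @return adjusted q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  check_numeric(pvalues[ok], "pvalues", lower = 0, upper = 1)
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's exact test for set overlap
#'
#' Two-sided exact test on the 2x2 table (set hits / set misses vs background
#' hits / background misses), with the sample odds ratio
#' \eqn{(a d)/(b c)}.
#'
#' @param set_hits,set_total,background_hits,background_total non-negative
#'   counts with hits <= totals.
#' @return list with `odds_ratio` (sample OR), `p`, `table`.
#' @export
fisher_overlap <- function(set_hits, set_total, background_hits, background_total) {
  counts <- c(set_hits, set_total, background_hits, background_total)
  if (any(counts < 0) || set_hits > set_total || background_hits > background_total) {
    rd_stop("counts must be non-negative with hits <= totals", "rd_value_error")
  }
  m <- matrix(c(set_hits, set_total - set_hits,
                background_hits, background_total - background_hits),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("set", "background"), c("hit", "miss")))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  p <- stats::fisher.test(m)$p.value
  list(odds_ratio = or, p = p, table = m)
}
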