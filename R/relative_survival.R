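#' Actuarial (life-table) observed survival
#'
#' Classical interval-actuarial estimator with the half-censoring
#' correction: within each interval the effective number at risk is the
#' number entering minus half the number censored there, the conditional
#' survival is `1 - deaths / n_eff`, and cumulative survival is the running
#' product. Greenwood's formula supplies the variance of log cumulative
#' survival.
#'
#' @param cohort data.frame of patient records with at least `time_years`
#'   and `event` (1 = died, 0 = censored).
#' @param interval_width interval width in years (default 1).
#' @param horizon total follow-up horizon in years.
#' @return data.frame with one row per interval: `interval_start`,
#'   `interval_end`, `at_risk`, `deaths`, `censored`, `n_eff`, `p_interval`
#'   (conditional survival), `surv` (cumulative observed survival) and
#'   `var_log_surv` (Greenwood variance of log `surv`).
#' @export
observed_survival <- function(cohort, interval_width = 1, horizon = 5) {
  if (is.null(cohort) || nrow(cohort) == 0)
    pm_stop("popmortgen_estimation_error", "cohort is empty")
  breaks <- seq(0, horizon, by = interval_width)
  if (length(breaks) < 2)
    pm_domain_error("horizon must cover at least one interval")
  k <- length(breaks) - 1
  out <- data.frame(interval_start = breaks[-length(breaks)],
                    interval_end = breaks[-1])
  t <- cohort$time_years
  ev <- cohort$event
  at_risk <- deaths <- censored <- numeric(k)
  for (j in seq_len(k)) {
    s <- out$interval_start[j]; e <- out$interval_end[j]
    at_risk[j] <- sum(t >= s)
    inside <- t >= s & t < e
    deaths[j] <- sum(inside & ev == 1)
    # administrative censoring exactly at the horizon counts as surviving
    censored[j] <- sum(inside & ev == 0)
  }
  n_eff <- at_risk - censored / 2
  p <- ifelse(n_eff > 0, 1 - deaths / n_eff, NA_real_)
  gw <- ifelse(n_eff > 0 & n_eff > deaths,
               deaths / (n_eff * (n_eff - deaths)), NA_real_)
  out$at_risk <- at_risk
  out$deaths <- deaths
  out$censored <- censored
  out$n_eff <- n_eff
  out$p_interval <- p
  out$surv <- cumprod(p)
  out$var_log_surv <- cumsum(gw)
  out
}

#' Ederer II expected survival
#'
#' Expected survival of a matched general population, computed the Ederer II
#' way: at the start of each interval, each patient still at risk
#' contributes their expected probability of surviving the interval — the
#' product of the annual population survival probabilities
#' `prob(year, sex, age)` along their trajectory, with attained age and
#' calendar year advancing by whole years. The interval's expected
#' conditional survival is the mean of those contributions over the risk
#' set, and cumulative expected survival is the running product. Attained
#' ages above the PopMort maximum continue at the maximum-age probability.
#'
#' @param cohort data.frame with `sex`, `entry_year`, `entry_age`,
#'   `time_years`, `event`.
#' @param pm a `popmort` object covering every (year, sex, age) any at-risk
#'   patient traverses.
#' @param interval_width interval width in whole years (default 1).
#' @param horizon follow-up horizon in whole years.
#' @return data.frame with `interval_start`, `interval_end`, `at_risk`,
#'   `p_interval` (expected conditional survival) and `surv` (cumulative
#'   expected survival).
#' @export
expected_survival_ederer2 <- function(cohort, pm, interval_width = 1,
                                      horizon = 5) {
  if (is.null(cohort) || nrow(cohort) == 0)
    pm_stop("popmortgen_estimation_error", "cohort is empty")
  if (interval_width != as.integer(interval_width) ||
      horizon != as.integer(horizon))
    pm_domain_error(
      "expected survival uses annual steps: interval_width and horizon must be whole years")
  lookup <- popmort_rate_lookup(pm)
  breaks <- seq(0L, as.integer(horizon), by = as.integer(interval_width))
  k <- length(breaks) - 1
  out <- data.frame(interval_start = breaks[-length(breaks)],
                    interval_end = breaks[-1])
  at_risk <- p_star <- numeric(k)
  for (j in seq_len(k)) {
    s <- out$interval_start[j]
    in_risk <- cohort$time_years >= s
    at_risk[j] <- sum(in_risk)
    if (!at_risk[j]) {
      p_star[j] <- NA_real_
      next
    }
    yrs_in_interval <- seq.int(s, out$interval_end[j] - 1L)
    indiv <- rep(1, at_risk[j])
    for (y in yrs_in_interval) {
      rate <- lookup(cohort$entry_year[in_risk] + y,
                     cohort$sex[in_risk],
                     cohort$entry_age[in_risk] + y)
      indiv <- indiv * exp(-rate)
    }
    p_star[j] <- mean(indiv)
  }
  out$at_risk <- at_risk
  out$p_interval <- p_star
  out$surv <- cumprod(p_star)
  out
}

#' Relative survival (observed / Ederer II expected)
#'
#' Cumulative relative survival per interval, with 95% confidence limits
#' obtained by a log(-log) transform of the observed-survival confidence
#' interval (Greenwood variance) and division of both limits by the
#' expected survival, which is treated as fixed.
#'
#' @inheritParams expected_survival_ederer2
#' @param conf_level confidence level (default 0.95).
#' @return An object of classes `rs_estimate` and `data.frame` with columns
#'   `interval_end`, `at_risk`, `observed`, `expected`, `relative`, `se`
#'   (delta-method standard error of `relative`), `ci_low`, `ci_high`.
#' @export
relative_survival <- function(cohort, pm, interval_width = 1, horizon = 5,
                              conf_level = 0.95) {
  obs <- observed_survival(cohort, interval_width, horizon)
  expd <- expected_survival_ederer2(cohort, pm, interval_width, horizon)
  if (any(expd$surv <= 0, na.rm = TRUE))
    pm_stop("popmortgen_estimation_error",
            "expected survival reached 0; relative survival undefined")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  s <- obs$surv
  v <- obs$var_log_surv
  lo <- hi <- rep(NA_real_, length(s))
  ok <- !is.na(s) & s > 0 & s < 1 & !is.na(v) & v > 0
  se_ll <- sqrt(v[ok]) / abs(log(s[ok]))
  lo[ok] <- s[ok]^exp(z * se_ll)
  hi[ok] <- s[ok]^exp(-z * se_ll)
  degen <- !is.na(s) & ((!is.na(v) & v == 0) | s %in% c(0, 1))
  lo[degen] <- hi[degen] <- s[degen]
  res <- data.frame(interval_end = obs$interval_end,
                    at_risk = obs$at_risk,
                    observed = s,
                    expected = expd$surv,
                    relative = s / expd$surv,
                    se = ifelse(is.na(v), NA_real_,
                                s * sqrt(v) / expd$surv),
                    ci_low = lo / expd$surv,
                    ci_high = hi / expd$surv)
  class(res) <- c("rs_estimate", "data.frame")
  res
}

#' Age-standardised relative survival
#'
#' Weighted average of age-group-specific relative survival per interval,
#' with the variance combined as the weighted sum of group variances
#' (weights squared). Weights are caller-supplied external standards (e.g.
#' ICSS weights), normalised to sum to 1. Groups with no at-risk patients in
#' any interval are dropped with a warning and the weights renormalised over
#' the remaining groups.
#'
#' @param estimates_by_group named list of `rs_estimate` data.frames (as
#'   returned by [relative_survival()]) on identical interval grids.
#' @param weights named non-negative numeric vector; names must match
#'   `estimates_by_group`.
#' @param conf_level confidence level for the normal-approximation interval.
#' @return An `rs_estimate` data.frame with `interval_end`, `relative`,
#'   `se`, `ci_low`, `ci_high`.
#' @export
age_standardised_rs <- function(estimates_by_group, weights,
                                conf_level = 0.95) {
  if (!length(estimates_by_group))
    pm_stop("popmortgen_estimation_error", "no age-group estimates supplied")
  if (is.null(names(estimates_by_group)) || is.null(names(weights)) ||
      !all(names(estimates_by_group) %in% names(weights)))
    pm_validation_error("weights must be named to match the age groups")
  if (any(weights < 0))
    pm_domain_error("standardisation weights must be non-negative")
  groups <- names(estimates_by_group)
  usable <- vapply(groups, function(g) {
    est <- estimates_by_group[[g]]
    all(est$at_risk > 0) && !anyNA(est$relative)
  }, logical(1))
  if (!all(usable)) {
    warning(sprintf(
      "dropping age group(s) with no at-risk patients: %s; weights renormalised",
      paste(groups[!usable], collapse = ", ")), call. = FALSE)
    groups <- groups[usable]
    if (!length(groups))
      pm_stop("popmortgen_estimation_error",
              "all age groups empty; cannot standardise")
  }
  w <- weights[groups]
  if (sum(w) <= 0)
    pm_domain_error("standardisation weights sum to zero")
  w <- w / sum(w)
  grid <- estimates_by_group[[groups[1]]]$interval_end
  for (g in groups)
    if (!identical(estimates_by_group[[g]]$interval_end, grid))
      pm_validation_error("age-group estimates are on different interval grids")
  rel <- sapply(groups, function(g) estimates_by_group[[g]]$relative)
  se <- sapply(groups, function(g) estimates_by_group[[g]]$se)
  rel <- matrix(rel, ncol = length(groups))
  se <- matrix(se, ncol = length(groups))
  asrs <- drop(rel %*% w)
  var_asrs <- drop(se^2 %*% w^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- data.frame(interval_end = grid,
                    relative = asrs,
                    se = sqrt(var_asrs),
                    ci_low = asrs - z * sqrt(var_asrs),
                    ci_high = asrs + z * sqrt(var_asrs))
  class(res) <- c("rs_estimate", "data.frame")
  res
}
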