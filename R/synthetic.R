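#' Parameters for synthetic life tables and cohorts
#'
#' Bundles the Gompertz-Makeham hazard parameters used to fabricate
#' abridged life tables, and the cohort-simulation settings used to draw
#' synthetic patients. The adult hazard is
#' \deqn{h(a) = A + B e^{C a}}
#' with `A` the age-independent (Makeham) component and `B`, `C` the
#' Gompertz scale and rate of ageing. Defaults give a schedule broadly
#' resembling a contemporary middle-income population (life expectancy in
#' the low 70s) and a cohort resembling a registry cancer series: diagnoses
#' 2013-2016, ages 45-80, five years of follow-up, excess (disease-specific)
#' hazard 0.1 per person-year.
#'
#' @param makeham_a baseline hazard per year (>= 0).
#' @param gompertz_b Gompertz scale per year (>= 0).
#' @param gompertz_c Gompertz rate of ageing per year of age (> 0).
#' @param seed integer RNG seed for cohort simulation.
#' @param cohort_n number of patients to simulate.
#' @param excess_hazard disease-specific hazard added to the population
#'   hazard, per person-year (>= 0).
#' @param entry_year_range,entry_age_range inclusive integer ranges for
#'   uniform entry year and age at diagnosis.
#' @param follow_up_years administrative censoring horizon (years).
#' @return An object of class `synthetic_params`.
#' @export
synthetic_params <- function(makeham_a = 5e-4,
                             gompertz_b = 2e-5,
                             gompertz_c = 0.1,
                             seed = 1L,
                             cohort_n = 1000L,
                             excess_hazard = 0.1,
                             entry_year_range = c(2013L, 2016L),
                             entry_age_range = c(45L, 80L),
                             follow_up_years = 5L) {
  if (makeham_a < 0 || gompertz_b < 0 || gompertz_c <= 0)
    pm_domain_error("hazard parameters must satisfy A >= 0, B >= 0, C > 0")
  if (excess_hazard < 0)
    pm_domain_error("excess_hazard must be non-negative")
  if (cohort_n < 1)
    pm_domain_error("cohort_n must be at least 1")
  h100 <- makeham_a + gompertz_b * exp(gompertz_c * 100)
  if (!is.finite(h100))
    pm_domain_error("hazard not finite at age 100")
  structure(list(makeham_a = makeham_a, gompertz_b = gompertz_b,
                 gompertz_c = gompertz_c, seed = as.integer(seed),
                 cohort_n = as.integer(cohort_n),
                 excess_hazard = excess_hazard,
                 entry_year_range = as.integer(entry_year_range),
                 entry_age_range = as.integer(entry_age_range),
                 follow_up_years = as.integer(follow_up_years)),
            class = "synthetic_params")
}

# Gompertz-Makeham cumulative hazard over [a1, a2).
gm_cumhaz <- function(params, a1, a2) {
  gomp <- if (params$gompertz_b > 0) {
    params$gompertz_b / params$gompertz_c *
      (exp(params$gompertz_c * a2) - exp(params$gompertz_c * a1))
  } else 0
  params$makeham_a * (a2 - a1) + gomp
}

#' Fabricate an abridged life table from a Gompertz-Makeham hazard
#'
#' Computes, for each five-year age group 0-4 through 90-94, the exact
#' probability of dying \eqn{{}_nq_x = 1 - \exp(-\int_x^{x+n} h(a)\,da)}
#' under the parameterised hazard (closed-form integral). Deterministic;
#' the seed is not used.
#'
#' @param params a [synthetic_params()] object.
#' @param period length-2 vector of calendar years (reference period).
#' @param sex sex code 1/2 (metadata only; supply different `params` per
#'   sex to model a differential).
#' @param width age-group width in years (default 5).
#' @param max_group_start starting age of the last closed group (default 90).
#' @return An `abridged_life_table`.
#' @export
make_life_table <- function(params, period, sex, width = 5L,
                            max_group_start = 90L) {
  starts <- seq.int(0L, max_group_start, by = width)
  H <- gm_cumhaz(params, starts, starts + width)
  nqx <- 1 - exp(-H)
  if (any(!is.finite(nqx)) || any(nqx >= 1))
    pm_domain_error(
      "hazard parameters yield nqx >= 1 in a closed age group")
  abridged_life_table(
    data.frame(age_start = starts, width_n = width, nqx = nqx),
    sex = sex, period_start = period[1], period_end = period[2],
    label = sprintf("synthetic GM(a=%g, b=%g, c=%g)",
                    params$makeham_a, params$gompertz_b, params$gompertz_c))
}

# rate lookup closure over a popmort object: rate(year, sex, age), with age
# capped at the table's maximum. Years outside coverage raise an error.
popmort_rate_lookup <- function(pm) {
  rec <- pm$records
  years <- sort(unique(rec$year))
  max_age <- max(rec$age)
  arr <- array(NA_real_, dim = c(length(years), 2L, max_age + 1L))
  arr[cbind(match(rec$year, years), rec$sex, rec$age + 1L)] <- rec$rate
  function(year, sex, age) {
    yi <- match(year, years)
    if (anyNA(yi)) {
      bad <- year[is.na(yi)][1]
      pm_stop("popmortgen_coverage_error", sprintf(
        "popmort does not cover calendar year %d (coverage %d-%d)",
        bad, min(years), max(years)))
    }
    arr[cbind(yi, sex, pmin(age, max_age) + 1L)]
  }
}

#' Simulate a patient cohort against a PopMort table
#'
#' Draws `cohort_n` patients with sex, entry year and entry age uniform over
#' the configured ranges, then simulates death times under the
#' piecewise-constant total hazard
#' `rate(entry_year + t, sex, entry_age + t) + excess_hazard`, advancing age
#' and calendar year in whole-year steps and censoring administratively at
#' `follow_up_years`. Ages beyond the table's maximum continue at the
#' maximum-age rate. Reproducible: the same seed yields the same cohort.
#'
#' @param pm a `popmort` object covering every calendar year any patient can
#'   reach (entry years through entry + follow-up).
#' @param params a [synthetic_params()] object.
#' @return data.frame with columns `id`, `sex`, `entry_year`, `entry_age`,
#'   `time_years` (follow-up in years), `event` (1 = died, 0 = censored).
#' @export
simulate_cohort <- function(pm, params) {
  validate_popmort(pm)
  lookup <- popmort_rate_lookup(pm)
  n <- params$cohort_n
  yrs <- sort(unique(pm$records$year))
  last_needed <- params$entry_year_range[2] + params$follow_up_years - 1L
  if (last_needed > max(yrs) || params$entry_year_range[1] < min(yrs))
    pm_stop("popmortgen_coverage_error", sprintf(
      "popmort years %d-%d do not cover entry %d-%d plus %d follow-up years",
      min(yrs), max(yrs), params$entry_year_range[1],
      params$entry_year_range[2], params$follow_up_years))

  set.seed(params$seed)
  sex <- sample(1:2, n, replace = TRUE)
  entry_year <- sample(seq.int(params$entry_year_range[1],
                               params$entry_year_range[2]), n, replace = TRUE)
  entry_age <- sample(seq.int(params$entry_age_range[1],
                              params$entry_age_range[2]), n, replace = TRUE)
  thresh <- stats::rexp(n)  # one exponential threshold per patient

  time <- rep(as.numeric(params$follow_up_years), n)
  event <- integer(n)
  cum <- numeric(n)
  alive <- rep(TRUE, n)
  for (t in seq_len(params$follow_up_years) - 1L) {
    if (!any(alive)) break
    h <- lookup(entry_year[alive] + t, sex[alive], entry_age[alive] + t) +
      params$excess_hazard
    new_cum <- cum[alive] + h
    dies <- new_cum >= thresh[alive]
    idx <- which(alive)
    die_idx <- idx[dies]
    if (length(die_idx)) {
      frac <- (thresh[die_idx] - cum[die_idx]) / h[dies]
      time[die_idx] <- t + frac
      event[die_idx] <- 1L
      alive[die_idx] <- FALSE
    }
    cum[idx] <- new_cum
  }
  data.frame(id = seq_len(n), sex = sex, entry_year = entry_year,
             entry_age = entry_age, time_years = time, event = event)
}

#' Write a cohort to delimited text
#'
#' @param cohort data.frame as returned by [simulate_cohort()].
#' @param path destination path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delimiter = ",") {
  lines <- c(paste(c("id", "sex", "entry_year", "entry_age", "time_years",
                     "event"), collapse = delimiter),
             paste(cohort$id, cohort$sex, cohort$entry_year,
                   cohort$entry_age, format_double(cohort$time_years),
                   cohort$event, sep = delimiter))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' @param path source path with columns `id`, `sex`, `entry_year`,
#'   `entry_age`, `time_years`, `event`.
#' @param delimiter field separator.
#' @return data.frame of cohort records.
#' @export
read_cohort <- function(path, delimiter = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE)
  need <- c("sex", "entry_year", "entry_age", "time_years", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    pm_validation_error(sprintf("cohort file lacks column(s): %s",
                                paste(missing, collapse = ", ")))
  if (nrow(df) == 0)
    pm_validation_error("cohort file contains no records")
  if (any(df$time_years < 0) || !all(df$event %in% 0:1) ||
      !all(df$sex %in% 1:2))
    pm_validation_error("cohort file has invalid sex, time or event values")
  df
}
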