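#' Convert a probability of dying to a central death rate
#'
#' Inverts the classical abridged life-table relation to recover the central
#' death rate \eqn{{}_nM_x} from the probability of dying \eqn{{}_nq_x}:
#' \deqn{{}_nM_x = \frac{{}_nq_x}{n - {}_nf_x \cdot {}_nq_x}}
#' where \eqn{n} is the interval width and \eqn{{}_nf_x} the separation
#' factor. Monotone increasing in `nqx`.
#'
#' @param nqx probability of dying within the interval, in \[0, 1).
#' @param width_n interval width in years (>= 1).
#' @param f separation factor (> 0), see [separation_factor()].
#' @return Central death rate per person-year (vectorised).
#' @seealso [rate_to_nqx()] for the forward relation (used as round-trip
#'   oracle), [rate_to_prob()].
#' @export
nqx_to_rate <- function(nqx, width_n, f) {
  if (any(nqx < 0 | nqx >= 1))
    pm_domain_error("nqx must lie in [0, 1) for rate conversion")
  if (any(width_n < 1) || any(f <= 0))
    pm_domain_error("width_n must be >= 1 and f > 0")
  denom <- width_n - f * nqx
  if (any(denom <= 0))
    pm_domain_error("non-positive denominator in nqx -> rate conversion (f * nqx >= width_n)")
  nqx / denom
}

#' Convert a central death rate to a probability of dying
#'
#' The forward relation
#' \deqn{{}_nq_x = \frac{n \cdot {}_nM_x}{1 + {}_nf_x \cdot {}_nM_x}}
#' It is the algebraic inverse of [nqx_to_rate()]. As the rate grows the
#' result approaches \eqn{n/f} (2 for five-year groups with \eqn{f = 5/2}),
#' so outputs can exceed 1 for extreme rates; callers constructing life
#' tables must clamp.
#'
#' @param rate central death rate per person-year (>= 0).
#' @inheritParams nqx_to_rate
#' @return Probability of dying within the interval, in \[0, n/f).
#' @export
rate_to_nqx <- function(rate, width_n, f) {
  if (any(rate < 0))
    pm_domain_error("rate must be non-negative")
  (width_n * rate) / (1 + f * rate)
}

#' Annual survival probability from a mortality rate
#'
#' `prob = exp(-rate)`: the probability of surviving one year under a
#' constant hazard equal to the central death rate. This is the `prob`
#' column of a PopMort file.
#'
#' @param rate mortality rate per person-year (>= 0).
#' @return Survival probability in (0, 1\] (vectorised).
#' @export
rate_to_prob <- function(rate) {
  if (any(rate < 0))
    pm_domain_error("rate must be non-negative")
  exp(-rate)
}

#' Midyear of a life-table reference period
#'
#' A life table published for a multi-year period is taken to best represent
#' the calendar year at the centre of that period: 2015-2019 represents
#' 2017, 2016-2020 represents 2018. Even-length periods round down.
#'
#' @param period_start,period_end calendar years, `period_start <= period_end`.
#' @return The midyear (integer).
#' @export
period_to_midyear <- function(period_start, period_end) {
  if (any(period_start > period_end))
    pm_domain_error("period_start must not exceed period_end")
  as.integer(floor((period_start + period_end) / 2))
}

#' Assign a source life table to each calendar year
#'
#' Maps every calendar year in `[start_year, end_year]` to the available
#' midyear at the smallest absolute distance. Years beyond the latest
#' midyear carry the latest table forward (the standard practice when recent
#' life tables are unavailable); years before the earliest midyear use the
#' earliest. Exact ties break toward the earlier midyear.
#'
#' @param midyears integer vector of midyears with available life tables.
#' @param start_year,end_year calendar-year range to cover.
#' @return Named integer vector: names are calendar years, values the
#'   midyear used for each.
#' @export
assign_years <- function(midyears, start_year, end_year) {
  if (length(midyears) == 0)
    pm_stop("popmortgen_config_error", "no life-table midyears available")
  if (start_year > end_year)
    pm_domain_error("start_year must not exceed end_year")
  mids <- sort(unique(as.integer(midyears)))
  years <- seq.int(start_year, end_year)
  assigned <- vapply(years, function(y) {
    d <- abs(mids - y)
    mids[which.min(d)]  # which.min takes the first minimum = earlier midyear
  }, integer(1))
  names(assigned) <- years
  assigned
}

#' Expand an abridged life table to single years of age
#'
#' Converts each closed age group's nqx to a central death rate (via
#' [nqx_to_rate()] with its separation factor) and an annual survival
#' probability, then assigns that rate and probability unchanged to every
#' single year of age in the group (piecewise-constant smoothing). Ages
#' beyond the last closed group — including any open terminal row, whose
#' nqx of 1 has no finite rate — reuse the last closed group's values up to
#' `max_age`.
#'
#' @param lt an `abridged_life_table` (first row starting at age 0; an
#'   SRS-style split infant row should be combined first with
#'   [merge_infant_rows()]).
#' @param max_age maximum single age to emit (default 100).
#' @param overrides optional separation-factor overrides, see
#'   [separation_factor()].
#' @return data.frame with `max_age + 1` rows and columns `age`, `rate`,
#'   `prob`, satisfying `prob == exp(-rate)` exactly.
#' @export
expand_to_single_ages <- function(lt, max_age = 100L, overrides = NULL) {
  validate_life_table(lt)
  r <- lt$rows[lt$rows$width_n > 0, , drop = FALSE]
  if (nrow(r) == 0)
    pm_validation_error("life table has no closed age groups")
  last_end <- r$age_start[nrow(r)] + r$width_n[nrow(r)] - 1L
  if (max_age < last_end)
    pm_domain_error(sprintf(
      "max_age %d is below the last closed group's end %d", max_age, last_end))
  f <- separation_factor(r$age_start, r$width_n, overrides)
  rate <- nqx_to_rate(r$nqx, r$width_n, f)
  prob <- rate_to_prob(rate)
  idx <- rep.int(seq_len(nrow(r)), r$width_n)
  n_tail <- max_age - last_end
  if (n_tail > 0)
    idx <- c(idx, rep.int(nrow(r), n_tail))
  data.frame(age = 0:max_age, rate = rate[idx], prob = prob[idx])
}

#' Build a PopMort table from abridged life tables
#'
#' Composes the full pipeline: combine split infant rows, convert nqx to
#' rates and annual survival probabilities, expand to single ages 0 to
#' `max_age`, assign each calendar year in `[start_year, end_year]` to its
#' nearest life-table midyear (with carry-forward/backfill at the edges),
#' and assemble one record per (year, sex, age). Deterministic.
#'
#' @param tables list of `abridged_life_table` objects; for every midyear in
#'   use, tables for both sexes must be present.
#' @param start_year,end_year calendar range to cover (first incidence year
#'   to last follow-up year).
#' @param max_age maximum single age (default 100).
#' @return An object of class `popmort`: list with `records` (data.frame of
#'   `year`, `sex`, `age`, `rate`, `prob`, sorted by year, sex, age) and
#'   `provenance` (data.frame mapping each year to the midyear, period and
#'   label of the life table used).
#' @examples
#' lt1 <- abridged_life_table(
#'   data.frame(age_start = c(0, 5), width_n = c(5, 5), nqx = c(0.01, 0.005)),
#'   sex = 1, period_start = 2016, period_end = 2020)
#' lt2 <- abridged_life_table(lt1$rows, sex = 2,
#'                            period_start = 2016, period_end = 2020)
#' pm <- build_popmort(list(lt1, lt2), 2018, 2018, max_age = 9)
#' nrow(pm$records)  # 1 year x 2 sexes x 10 ages = 20
#' @export
build_popmort <- function(tables, start_year, end_year, max_age = 100L) {
  if (start_year > end_year)
    pm_domain_error("start_year must not exceed end_year")
  if (!length(tables))
    pm_validation_error("no life tables supplied")
  for (lt in tables) validate_life_table(lt)

  mid <- vapply(tables, function(lt)
    period_to_midyear(lt$period_start, lt$period_end), integer(1))
  sex <- vapply(tables, function(lt) lt$sex, integer(1))

  year_map <- assign_years(unique(mid), start_year, end_year)
  expansions <- list()   # keyed "midyear/sex"
  prov_rows <- list()
  for (m in unique(year_map)) {
    for (sx in 1:2) {
      hit <- which(mid == m & sex == sx)
      if (!length(hit))
        pm_stop("popmortgen_completeness_error", sprintf(
          "no life table for sex %d covering midyear %d", sx, m),
          midyear = m, sex = sx)
      lt <- tables[[hit[1]]]
      if (lt$rows$width_n[1] == 1)
        lt <- merge_infant_rows(lt)
      expansions[[paste(m, sx)]] <- expand_to_single_ages(lt, max_age)
      if (sx == 1)
        prov_rows[[as.character(m)]] <- data.frame(
          midyear = m,
          period = sprintf("%d-%d", lt$period_start, lt$period_end),
          label = lt$label)
    }
  }

  years <- as.integer(names(year_map))
  blocks <- lapply(seq_along(years), function(i) {
    m <- year_map[i]
    do.call(rbind, lapply(1:2, function(sx) {
      e <- expansions[[paste(m, sx)]]
      data.frame(year = years[i], sex = sx, age = e$age,
                 rate = e$rate, prob = e$prob)
    }))
  })
  records <- do.call(rbind, blocks)
  records <- records[order(records$year, records$sex, records$age), ]
  rownames(records) <- NULL

  prov <- do.call(rbind, prov_rows[as.character(year_map)])
  provenance <- data.frame(year = years, prov, row.names = NULL)

  structure(list(records = records, provenance = provenance,
                 max_age = as.integer(max_age)),
            class = "popmort")
}

#' Validate a PopMort table
#'
#' Checks completeness (exactly one record per (year, sex, age) with ages
#' 0..max contiguous for every year and sex) and the probability link
#' `prob = exp(-rate)` within `tol`.
#'
#' @param pm a `popmort` object.
#' @param tol absolute tolerance on `prob - exp(-rate)` (default 0, exact;
#'   file readers relax this to absorb text round-tripping).
#' @return `pm`, invisibly.
#' @export
validate_popmort <- function(pm, tol = 0) {
  rec <- pm$records
  need <- c("year", "sex", "age", "rate", "prob")
  if (!all(need %in% names(rec)))
    pm_validation_error("popmort records missing required columns")
  ages <- sort(unique(rec$age))
  max_age <- max(ages)
  if (!identical(as.integer(ages), 0:max_age))
    pm_validation_error("ages are not contiguous from 0")
  years <- sort(unique(rec$year))
  expected_n <- length(years) * 2L * (max_age + 1L)
  if (nrow(rec) != expected_n || anyDuplicated(rec[c("year", "sex", "age")]))
    pm_validation_error(sprintf(
      "popmort incomplete: expected %d unique (year, sex, age) records, found %d rows",
      expected_n, nrow(rec)))
  cnt <- table(rec$year, rec$sex)
  if (any(cnt != max_age + 1L)) {
    bad <- which(cnt != max_age + 1L, arr.ind = TRUE)[1, ]
    pm_validation_error(sprintf(
      "popmort incomplete for year %s, sex %s",
      rownames(cnt)[bad[1]], colnames(cnt)[bad[2]]))
  }
  dev <- abs(rec$prob - exp(-rec$rate))
  if (any(dev > tol)) {
    i <- which.max(dev)
    pm_validation_error(sprintf(
      "prob != exp(-rate) at (year %d, sex %d, age %d): |diff| = %g",
      rec$year[i], rec$sex[i], rec$age[i], dev[i]))
  }
  invisible(pm)
}

#' @export
print.popmort <- function(x, ...) {
  rec <- x$records
  cat(sprintf("PopMort table: years %d-%d, ages 0-%d, both sexes (%d records)\n",
              min(rec$year), max(rec$year), max(rec$age), nrow(rec)))
  cat("Year -> life table provenance:\n")
  print(x$provenance, row.names = FALSE)
  invisible(x)
}
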