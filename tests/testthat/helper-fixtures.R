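# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# standard 5-year life table from an nqx vector (0-4, 5-9, ..., then an
# optional open terminal row)
lt_from_nqx <- function(nqx, sex = 1, period = c(2016, 2020), open = FALSE,
                        label = "fixture") {
  k <- length(nqx) - if (open) 1L else 0L
  rows <- data.frame(age_start = seq.int(0L, by = 5L, length.out = k),
                     width_n = 5L,
                     nqx = nqx[seq_len(k)])
  if (open)
    rows <- rbind(rows, data.frame(age_start = 5L * k, width_n = 0L,
                                   nqx = nqx[k + 1L]))
  abridged_life_table(rows, sex = sex, period_start = period[1],
                      period_end = period[2], label = label)
}

# popmort with one constant rate per sex, built directly (not via
# build_popmort) so relative-survival tests have an independent input path
const_popmort <- function(years, rate_male, rate_female = rate_male,
                          max_age = 100L) {
  grid <- expand.grid(age = 0:max_age, sex = 1:2, year = years)
  rate <- ifelse(grid$sex == 1, rate_male, rate_female)
  rec <- data.frame(year = grid$year, sex = grid$sex, age = grid$age,
                    rate = rate, prob = exp(-rate))
  rec <- rec[order(rec$year, rec$sex, rec$age), ]
  rownames(rec) <- NULL
  structure(list(records = rec, provenance = data.frame(),
                 max_age = as.integer(max_age)),
            class = "popmort")
}

# minimal cohort data.frame
cohort_df <- function(time_years, event, sex = 1, entry_year = 2013,
                      entry_age = 60) {
  n <- length(time_years)
  data.frame(id = seq_len(n), sex = rep_len(sex, n),
             entry_year = rep_len(entry_year, n),
             entry_age = rep_len(entry_age, n),
             time_years = time_years, event = event)
}

# tiny two-group table pair (closed groups 0-4 and 5-9) for tests that
# build popmorts with a small max_age
small_pair <- function(period = c(2015, 2019)) {
  list(lt_from_nqx(c(0.01, 0.005), sex = 1, period = period),
       lt_from_nqx(c(0.009, 0.004), sex = 2, period = period))
}

# default synthetic life tables for both sexes over two periods, as used by
# several end-to-end tests
default_synth_tables <- function() {
  p <- synthetic_params()
  list(make_life_table(p, c(2015, 2019), sex = 1),
       make_life_table(p, c(2015, 2019), sex = 2),
       make_life_table(p, c(2016, 2020), sex = 1),
       make_life_table(p, c(2016, 2020), sex = 2))
}
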