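test_that("wide-format life tables parse into one table per sex", {
  path <- withr::local_tempfile(fileext = ".csv")
  labels <- c(sprintf("%d-%d", seq(0, 80, 5), seq(4, 84, 5)), "85+")
  qm <- c(seq(0.012, 0.095, length.out = 17), 1)
  qf <- c(seq(0.010, 0.090, length.out = 17), 1)
  writeLines(c("age_group,nqx_m,nqx_f",
               paste(labels, qm, qf, sep = ",")), path)
  tabs <- parse_life_table(path, list(
    age_col = "age_group", nqx_cols = c("1" = "nqx_m", "2" = "nqx_f"),
    period_start = 2016, period_end = 2020))
  expect_length(tabs, 2)
  expect_equal(vapply(tabs, `[[`, integer(1), "sex"), 1:2)
  expect_equal(nrow(tabs[[1]]$rows), 18)
  expect_equal(tabs[[1]]$rows$nqx, qm)
  # "85+" -> open terminal group
  expect_equal(tabs[[1]]$rows$age_start[18], 85)
  expect_equal(tabs[[1]]$rows$width_n[18], 0)
})

test_that("long-format parsing with a textual sex column and sex_map works", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group\tq\twho",
               "0-4\t0.01\tM", "5-9\t0.004\tM",
               "0-4\t0.009\tF", "5-9\t0.003\tF"), path)
  tabs <- parse_life_table(path, list(
    age_col = "group", nqx_col = "q", sex_col = "who",
    sex_map = c(M = 1, F = 2),
    period_start = 2015, period_end = 2019))
  expect_length(tabs, 2)
  expect_equal(tabs[[2]]$sex, 2L)
  expect_equal(tabs[[2]]$rows$nqx, c(0.009, 0.003))
})

test_that("label dialects: en dash, bare integers with inferred width", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_group,q", "0–4,0.01", "5,0.004", "10,0.003",
               "15–19,0.005"), path)
  tabs <- parse_life_table(path, list(
    age_col = "age_group", nqx_cols = c("1" = "q"),
    period_start = 2016, period_end = 2020))
  expect_equal(tabs[[1]]$rows$age_start, c(0, 5, 10, 15))
  expect_equal(tabs[[1]]$rows$width_n, c(5, 5, 5, 5))
})

test_that("parse errors are structured and name the offending row/column", {
  bad_nqx <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_group,q", "0-4,0.01", "5-9,1.2"), bad_nqx)
  schema <- list(age_col = "age_group", nqx_cols = c("1" = "q"),
                 period_start = 2016, period_end = 2020)
  err <- expect_error(parse_life_table(bad_nqx, schema),
                      "outside \\[0,1\\]",
                      class = "popmortgen_parse_error")
  expect_equal(err$row, 2)
  expect_equal(err$column, "q")

  gap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_group,q", "0-4,0.01", "10-14,0.003"), gap)
  expect_error(parse_life_table(gap, schema), "contiguous",
               class = "popmortgen_parse_error")

  junk <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_group,q", "zero to four,0.01"), junk)
  expect_error(parse_life_table(junk, schema), "unparseable",
               class = "popmortgen_parse_error")

  bare_last <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_group,q", "0-4,0.01", "5,0.004"), bare_last)
  expect_error(parse_life_table(bare_last, schema), "cannot infer width",
               class = "popmortgen_parse_error")

  expect_error(parse_life_table(bad_nqx, list(age_col = "age_group",
                                              period_start = 1, period_end = 2)),
               "nqx_cols", class = "popmortgen_parse_error")

  no_sex_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age_group,q,sex", "0-4,0.01,3"), no_sex_col)
  expect_error(parse_life_table(no_sex_col, list(
    age_col = "age_group", nqx_col = "q", sex_col = "sex",
    period_start = 2016, period_end = 2020)),
    "not 1 or 2", class = "popmortgen_parse_error")
})

test_that("serialise -> parse round-trips nqx bit-for-bit", {
  set.seed(42)
  for (i in 1:5) {
    q <- c(sort(runif(18, 0, 0.6)), 1)
    lt <- lt_from_nqx(q, open = TRUE)
    path <- withr::local_tempfile(fileext = ".csv")
    write_life_table(lt, path)
    back <- parse_life_table(path, list(
      age_col = "age_group", nqx_cols = c("1" = "nqx"),
      period_start = 2016, period_end = 2020))[[1]]
    expect_identical(back$rows$nqx, lt$rows$nqx)
    expect_identical(back$rows$age_start, lt$rows$age_start)
    expect_identical(back$rows$width_n, lt$rows$width_n)
  }
})

test_that("life-table validation rejects malformed tables", {
  good <- data.frame(age_start = c(0, 5), width_n = c(5, 5),
                     nqx = c(0.01, 0.02))
  expect_error(abridged_life_table(good, sex = 3, 2016, 2020),
               "sex code", class = "popmortgen_validation_error")
  expect_error(abridged_life_table(good, sex = 1, 2020, 2016),
               "period_start", class = "popmortgen_validation_error")
  expect_error(abridged_life_table(
    data.frame(age_start = c(5, 10), width_n = 5, nqx = 0.1), 1, 2016, 2020),
    "start at age 0", class = "popmortgen_validation_error")
  # nqx = 1 in a closed group is rejected; fine in the open group
  expect_error(abridged_life_table(
    data.frame(age_start = c(0, 5), width_n = c(5, 5), nqx = c(0.01, 1)),
    1, 2016, 2020), "open terminal",
    class = "popmortgen_validation_error")
  expect_s3_class(abridged_life_table(
    data.frame(age_start = c(0, 5), width_n = c(5, 0), nqx = c(0.01, 1)),
    1, 2016, 2020), "abridged_life_table")
})

test_that("merge_infant_rows combines 0 and 1-4 via the survival product", {
  split_lt <- abridged_life_table(
    data.frame(age_start = c(0, 1, 5, 10), width_n = c(1, 4, 5, 5),
               nqx = c(0.03, 0.01, 0.004, 0.003)),
    sex = 1, period_start = 2016, period_end = 2020)
  merged <- merge_infant_rows(split_lt)
  expect_equal(merged$rows$nqx[1], 1 - 0.97 * 0.99)  # 0.0397 by hand
  expect_equal(merged$rows$width_n[1], 5)
  # rows from age 5 on are untouched
  expect_equal(merged$rows[-1, ], split_lt$rows[-(1:2), ],
               ignore_attr = TRUE)
  # idempotent
  expect_identical(merge_infant_rows(merged), merged)
  # zero mortality merges to zero
  z <- abridged_life_table(
    data.frame(age_start = c(0, 1), width_n = c(1, 4), nqx = c(0, 0)),
    1, 2016, 2020)
  expect_equal(merge_infant_rows(z)$rows$nqx, 0)
  # anything else is a schema error
  odd <- abridged_life_table(
    data.frame(age_start = c(0, 1), width_n = c(1, 1), nqx = c(0.1, 0.1)),
    1, 2016, 2020)
  expect_error(merge_infant_rows(odd), class = "popmortgen_schema_error")
})

test_that("separation factors follow the 1/2 (0-4) and n/2 rule", {
  expect_equal(separation_factor(0, 5), 0.5)
  expect_equal(separation_factor(5, 5), 2.5)
  expect_equal(separation_factor(80, 5), 2.5)
  # n/2 everywhere except the combined infant group
  starts <- seq(5, 90, 5)
  expect_equal(separation_factor(starts, rep(5, length(starts))),
               rep(2.5, length(starts)))
  expect_equal(separation_factor(0, 1), 0.5)   # width 1: n/2 rule
  expect_equal(separation_factor(10, 10), 5)
  expect_error(separation_factor(85, 0), class = "popmortgen_domain_error")
  # override table wins
  ov <- data.frame(age_start = 0, factor = 0.3)
  expect_equal(separation_factor(0, 5, overrides = ov), 0.3)
  expect_equal(separation_factor(5, 5, overrides = ov), 2.5)
})
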