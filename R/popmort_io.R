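#' Column layout of a PopMort file
#'
#' The default headers (`_year`, `sex`, `_age`, `rate`, `prob`) follow the
#' naming convention expected by common relative-survival software, where
#' the popmort file is merged onto patient data by attained year, sex and
#' attained age.
#'
#' @param year,sex,age,rate,prob column headers for the five roles.
#' @param delimiter field separator (default comma).
#' @return An object of class `popmort_file_spec`.
#' @export
popmort_file_spec <- function(year = "_year", sex = "sex", age = "_age",
                              rate = "rate", prob = "prob",
                              delimiter = ",") {
  headers <- c(year = year, sex = sex, age = age, rate = rate, prob = prob)
  if (anyDuplicated(headers))
    pm_validation_error("popmort file spec maps two roles to the same header")
  structure(list(headers = headers, delimiter = delimiter),
            class = "popmort_file_spec")
}

# %.17g is a round-trippable decimal representation of a double; output is
# locale-independent (C formatting, "." decimal point).
format_double <- function(x) {
  out <- sprintf("%.17g", x)
  # trim trailing zeros that %.17g leaves on exactly-representable values
  short <- sprintf("%.15g", x)
  ifelse(as.numeric(short) == x, short, out)
}

#' Write a PopMort table to delimited text
#'
#' Writes a header row plus one row per (year, sex, age) record, sorted by
#' year, sex, age. Numbers are serialised with a round-trippable decimal
#' representation so that write -> read -> write is byte-identical.
#'
#' @param pm a `popmort` object satisfying [validate_popmort()].
#' @param path destination path.
#' @param spec a [popmort_file_spec()].
#' @return Number of data rows written, invisibly.
#' @export
write_popmort <- function(pm, path, spec = popmort_file_spec()) {
  validate_popmort(pm)
  rec <- pm$records[order(pm$records$year, pm$records$sex, pm$records$age), ]
  d <- spec$delimiter
  lines <- c(paste(spec$headers, collapse = d),
             paste(rec$year, rec$sex, rec$age,
                   format_double(rec$rate), format_double(rec$prob),
                   sep = d))
  con <- file(path, open = "wb")  # fixed newlines across platforms
  on.exit(close(con))
  writeLines(lines, con)
  invisible(nrow(rec))
}

#' Read a PopMort table from delimited text
#'
#' Reconstructs a `popmort` object and validates its invariants:
#' completeness of the (year, sex, age) cross-product and consistency of
#' `prob` with `exp(-rate)` within `1e-9` (absorbing decimal
#' round-tripping).
#'
#' @param path source path, written by [write_popmort()] or matching `spec`.
#' @param spec a [popmort_file_spec()].
#' @return A `popmort` object (provenance is not stored in the file and is
#'   returned empty).
#' @export
read_popmort <- function(path, spec = popmort_file_spec()) {
  df <- utils::read.table(path, header = TRUE, sep = spec$delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(spec$headers), names(df))
  if (length(missing))
    pm_validation_error(sprintf("popmort file lacks column(s): %s",
                                paste(missing, collapse = ", ")))
  rec <- data.frame(year = as.integer(df[[spec$headers["year"]]]),
                    sex = as.integer(df[[spec$headers["sex"]]]),
                    age = as.integer(df[[spec$headers["age"]]]),
                    rate = as.numeric(df[[spec$headers["rate"]]]),
                    prob = as.numeric(df[[spec$headers["prob"]]]))
  rec <- rec[order(rec$year, rec$sex, rec$age), ]
  rownames(rec) <- NULL
  pm <- structure(list(records = rec,
                       provenance = data.frame(),
                       max_age = max(rec$age)),
                  class = "popmort")
  validate_popmort(pm, tol = 1e-9)
  pm
}
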