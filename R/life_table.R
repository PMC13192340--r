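#' Construct an abridged life table
#'
#' An abridged life table carries, for one sex and one reference period, the
#' probability of dying within each age group (\eqn{{}_nq_x}) for an ordered,
#' contiguous set of age groups starting at age 0. This is the form in which
#' sample-survey life tables (e.g. India's Sample Registration System) are
#' published; it is the sole input to the PopMort conversion.
#'
#' @param rows data.frame with columns `age_start` (integer years),
#'   `width_n` (interval length in years; `0` marks the open terminal group)
#'   and `nqx` (probability of dying in the interval, in \[0,1\]).
#' @param sex sex code: `1` = male, `2` = female.
#' @param period_start,period_end calendar years of the reference period.
#' @param label free-text provenance label (e.g. "rural Punjab").
#' @return An object of class `abridged_life_table`.
#' @examples
#' lt <- abridged_life_table(
#'   data.frame(age_start = c(0, 5, 10), width_n = c(5, 5, 5),
#'              nqx = c(0.012, 0.0035, 0.003)),
#'   sex = 1, period_start = 2016, period_end = 2020)
#' @export
abridged_life_table <- function(rows, sex, period_start, period_end,
                                label = "") {
  lt <- structure(
    list(rows = as.data.frame(rows)[, c("age_start", "width_n", "nqx")],
         sex = as.integer(sex),
         period_start = as.integer(period_start),
         period_end = as.integer(period_end),
         label = as.character(label)),
    class = "abridged_life_table")
  validate_life_table(lt)
  lt
}

#' Validate an abridged life table
#'
#' Checks the structural invariants: non-empty contiguous rows starting at
#' age 0, nqx within \[0,1\] (nqx = 1 only allowed for the open terminal
#' group), at most one open group and only in last position, sex code in
#' \{1, 2\}, and an ordered period.
#'
#' @param lt an `abridged_life_table`.
#' @return `lt`, invisibly, if valid; otherwise a validation error.
#' @export
validate_life_table <- function(lt) {
  r <- lt$rows
  if (nrow(r) == 0)
    pm_validation_error("life table has no rows")
  if (!lt$sex %in% c(1L, 2L))
    pm_validation_error(sprintf("sex code must be 1 (male) or 2 (female), got %s",
                                lt$sex))
  if (lt$period_start > lt$period_end)
    pm_validation_error(sprintf("period_start %d exceeds period_end %d",
                                lt$period_start, lt$period_end))
  if (r$age_start[1] != 0)
    pm_validation_error("first age group must start at age 0")
  if (any(is.na(r$nqx)) || any(r$nqx < 0) || any(r$nqx > 1))
    pm_validation_error(sprintf(
      "nqx outside [0,1] at row %d",
      which(is.na(r$nqx) | r$nqx < 0 | r$nqx > 1)[1]))
  open <- which(r$width_n == 0)
  if (length(open) > 1 || (length(open) == 1 && open != nrow(r)))
    pm_validation_error("open age group (width 0) only allowed as the last row")
  closed <- r$width_n > 0
  if (any(r$width_n[closed] < 1))
    pm_validation_error("closed age groups must have width >= 1")
  if (any(r$nqx == 1 & closed))
    pm_validation_error(sprintf(
      "nqx = 1 only permitted in the open terminal group (row %d)",
      which(r$nqx == 1 & closed)[1]))
  if (nrow(r) > 1) {
    expected <- r$age_start[-nrow(r)] + r$width_n[-nrow(r)]
    bad <- which(r$age_start[-1] != expected)
    if (length(bad))
      pm_validation_error(sprintf(
        "age groups not contiguous: row %d starts at %d, expected %d",
        bad[1] + 1, r$age_start[bad[1] + 1], expected[bad[1]]))
  }
  invisible(lt)
}

#' @export
print.abridged_life_table <- function(x, ...) {
  cat(sprintf("Abridged life table%s: sex %d, period %d-%d, %d age groups\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$sex, x$period_start, x$period_end, nrow(x$rows)))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

# "0-4", "5–9" (en dash), "85+" or bare "0". Returns list(age_start,
# width_n) with width_n NA for bare integers (inferred later) and 0 for "+".
parse_age_group_label <- function(label, row = NA) {
  s <- gsub("–|—", "-", trimws(as.character(label)))
  if (grepl("^[0-9]+\\s*\\+$", s)) {
    return(list(age_start = as.integer(sub("\\+", "", s)), width_n = 0L))
  }
  if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", s)) {
    ab <- as.integer(strsplit(s, "\\s*-\\s*")[[1]])
    if (ab[2] < ab[1])
      pm_parse_error(sprintf("age group '%s' ends before it starts (row %s)",
                             label, row), row = row)
    # "0-4" spans ages 0..4, i.e. width 5
    return(list(age_start = ab[1], width_n = ab[2] - ab[1] + 1L))
  }
  if (grepl("^[0-9]+$", s)) {
    return(list(age_start = as.integer(s), width_n = NA_integer_))
  }
  pm_parse_error(sprintf("unparseable age-group label '%s' (row %s)",
                         label, row), row = row)
}

# Guess comma vs tab from the header line unless the schema fixes it.
detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Parse abridged life tables from delimited text
#'
#' Reads a delimiter-separated table with one row per age group and returns
#' one `abridged_life_table` per (sex, period). Two layouts are supported,
#' selected by the schema:
#' \itemize{
#'   \item wide: one nqx column per sex (`nqx_cols = c("1" = "...", "2" = "...")`),
#'   \item long: a single nqx column plus a sex-indicator column
#'     (`nqx_col`, `sex_col`, and optionally `sex_map` translating textual
#'     codes to 1/2).
#' }
#' Age-group labels of the forms `"0-4"`, `"5–9"` (en dash), `"85+"` and
#' bare integers (width inferred from the next row) are accepted.
#'
#' @param source path to a delimited text file.
#' @param schema a list with entries `age_col`, either `nqx_cols` or
#'   `nqx_col` + `sex_col` (+ optional `sex_map`, a named vector mapping
#'   textual sex labels to codes 1/2), `period_start`, `period_end`, and
#'   optionally `label` and `delimiter`.
#' @return A list of `abridged_life_table` objects, one per (sex, period).
#' @seealso [merge_infant_rows()], [build_popmort()]
#' @export
parse_life_table <- function(source, schema) {
  for (field in c("age_col", "period_start", "period_end"))
    if (is.null(schema[[field]]))
      pm_parse_error(sprintf("schema is missing '%s'", field))
  delim <- schema$delimiter %||% detect_delimiter(source)
  df <- utils::read.table(source, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  need_col <- function(col) {
    if (!col %in% names(df))
      pm_parse_error(sprintf("column '%s' not found in %s", col, source),
                     column = col)
    col
  }
  need_col(schema$age_col)

  build_rows <- function(age_labels, nqx_chr, col) {
    parsed <- lapply(seq_along(age_labels), function(i)
      parse_age_group_label(age_labels[i], row = i))
    age_start <- vapply(parsed, `[[`, integer(1), "age_start")
    width_n <- vapply(parsed, `[[`, integer(1), "width_n")
    for (i in which(is.na(width_n))) {
      if (i == length(width_n))
        pm_parse_error(sprintf(
          "cannot infer width of bare age label '%s' in the last row (row %d)",
          age_labels[i], i), row = i)
      width_n[i] <- age_start[i + 1] - age_start[i]
    }
    nqx <- suppressWarnings(as.numeric(nqx_chr))
    bad <- which(is.na(nqx) | nqx < 0 | nqx > 1)
    if (length(bad))
      pm_parse_error(sprintf(
        "nqx value '%s' outside [0,1] (row %d, column '%s')",
        nqx_chr[bad[1]], bad[1], col), row = bad[1], column = col)
    data.frame(age_start = age_start, width_n = width_n, nqx = nqx)
  }

  make_lt <- function(rows, sex) {
    lt <- tryCatch(
      abridged_life_table(rows, sex = sex,
                          period_start = schema$period_start,
                          period_end = schema$period_end,
                          label = schema$label %||% basename(source)),
      popmortgen_validation_error = function(e)
        pm_parse_error(sprintf("invalid life table for sex %d: %s",
                               sex, conditionMessage(e))))
    lt
  }

  if (!is.null(schema$nqx_cols)) {
    cols <- schema$nqx_cols
    if (is.null(names(cols)) || !all(names(cols) %in% c("1", "2")))
      pm_parse_error("schema$nqx_cols must be named with sex codes \"1\"/\"2\"")
    lapply(names(cols), function(sx) {
      col <- need_col(cols[[sx]])
      make_lt(build_rows(df[[schema$age_col]], df[[col]], col),
              as.integer(sx))
    })
  } else if (!is.null(schema$nqx_col) && !is.null(schema$sex_col)) {
    need_col(schema$nqx_col); need_col(schema$sex_col)
    sex_raw <- df[[schema$sex_col]]
    sex <- if (!is.null(schema$sex_map)) {
      unknown <- setdiff(unique(sex_raw), names(schema$sex_map))
      if (length(unknown))
        pm_parse_error(sprintf("sex label '%s' not covered by schema$sex_map",
                               unknown[1]), column = schema$sex_col)
      as.integer(schema$sex_map[sex_raw])
    } else {
      suppressWarnings(as.integer(sex_raw))
    }
    if (any(is.na(sex) | !sex %in% c(1L, 2L)))
      pm_parse_error(sprintf("sex code '%s' is not 1 or 2 (row %d)",
                             sex_raw[which(is.na(sex) | !sex %in% 1:2)[1]],
                             which(is.na(sex) | !sex %in% 1:2)[1]),
                     column = schema$sex_col)
    lapply(sort(unique(sex)), function(sx) {
      sel <- sex == sx
      make_lt(build_rows(df[[schema$age_col]][sel],
                         df[[schema$nqx_col]][sel], schema$nqx_col), sx)
    })
  } else {
    pm_parse_error(
      "schema must supply either nqx_cols or both nqx_col and sex_col")
  }
}

#' Serialise an abridged life table to delimited text
#'
#' Writes one row per age group with columns `age_group` (label in `a-b` /
#' `a+` form) and `nqx` at full precision, so that parsing the output
#' reproduces the nqx values bit for bit.
#'
#' @param lt an `abridged_life_table`.
#' @param path destination path.
#' @param delimiter field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path, delimiter = ",") {
  validate_life_table(lt)
  r <- lt$rows
  label <- ifelse(r$width_n == 0,
                  sprintf("%d+", r$age_start),
                  sprintf("%d-%d", r$age_start, r$age_start + r$width_n - 1L))
  lines <- c(paste("age_group", "nqx", sep = delimiter),
             paste(label, sprintf("%.17g", r$nqx), sep = delimiter))
  writeLines(lines, path)
  invisible(path)
}

#' Merge separate infant (0) and child (1-4) rows into one 0-4 group
#'
#' SRS-style tables split the first five years of life into an infant row
#' (age 0, width 1) and a child row (ages 1-4, width 4), while the
#' separation-factor rule used for rate conversion is stated for a combined
#' 0-4 group. This merges the two rows using the survival product
#' \eqn{q = 1 - (1 - q_0)(1 - {}_4q_1)}. Tables already starting with a
#' 0-4 group are returned unchanged (the operation is idempotent).
#'
#' @param lt an `abridged_life_table` whose first rows are (0, width 1) and
#'   (1, width 4), or whose first row already spans 0-4.
#' @return An `abridged_life_table` with a combined first row.
#' @export
merge_infant_rows <- function(lt) {
  validate_life_table(lt)
  r <- lt$rows
  if (r$age_start[1] == 0 && r$width_n[1] == 5)
    return(lt)
  if (nrow(r) >= 2 && r$width_n[1] == 1 && r$age_start[2] == 1 &&
      r$width_n[2] == 4) {
    q <- 1 - (1 - r$nqx[1]) * (1 - r$nqx[2])
    rows <- rbind(data.frame(age_start = 0L, width_n = 5L, nqx = q),
                  r[-(1:2), , drop = FALSE])
    rownames(rows) <- NULL
    return(abridged_life_table(rows, lt$sex, lt$period_start, lt$period_end,
                               lt$label))
  }
  pm_stop("popmortgen_schema_error", sprintf(
    "cannot merge infant rows: first rows are (%d, width %d)/(%s, width %s), expected (0,1)+(1,4) or a combined (0,5)",
    r$age_start[1], r$width_n[1],
    if (nrow(r) >= 2) r$age_start[2] else "-",
    if (nrow(r) >= 2) r$width_n[2] else "-"))
}

#' Separation factor for an age group
#'
#' The separation factor \eqn{{}_nf_x} expresses the average timing of
#' deaths within an age interval and drives the interconversion between the
#' probability of dying \eqn{{}_nq_x} and the central death rate
#' \eqn{{}_nM_x}. The convention implemented here is 1/2 for the combined
#' 0-4 group (infant deaths cluster early in the interval) and n/2 for every
#' other closed group — 5/2 for the standard five-year groups.
#'
#' @param age_start starting age of the group (years).
#' @param width_n interval width in years; must be >= 1 (closed group).
#' @param overrides optional data.frame with columns `age_start` and
#'   `factor` taking precedence over the default rule.
#' @return The separation factor (scalar, vectorised over inputs).
#' @examples
#' separation_factor(0, 5)   # 0.5
#' separation_factor(5, 5)   # 2.5
#' @export
separation_factor <- function(age_start, width_n, overrides = NULL) {
  if (any(width_n < 1))
    pm_domain_error(
      "separation factor is undefined for the open terminal group (width 0)")
  f <- ifelse(age_start == 0 & width_n == 5, 0.5, width_n / 2)
  if (!is.null(overrides)) {
    m <- match(age_start, overrides$age_start)
    f[!is.na(m)] <- overrides$factor[m[!is.na(m)]]
  }
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a
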