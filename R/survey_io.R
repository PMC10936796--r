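# Reading, validating and writing the three survey tables.
#
# All tables are delimited text with a header row (comma by default, tab
# selectable). Missing numeric fields are an empty cell or the dialect's
# missing token -- never sentinel numbers. Reading never silently drops
# data: every rejected row is tallied in the attached report, and
# accepted + rejected always equals rows read.

#' Delimited-text dialect
#'
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param na missing-value token (an empty cell is always also missing).
#' @param sex_codes named map from file codes to `male`/`female`/`unknown`.
#' @return list of class `"io_dialect"`.
#' @export
io_dialect <- function(sep = ",", na = "NA",
                       sex_codes = c(M = "male", F = "female", U = "unknown")) {
  structure(list(sep = sep, na = na, sex_codes = sex_codes),
            class = "io_dialect")
}

#' Per-file read report
#'
#' Accessor for the rejection report attached to a table returned by
#' [read_stations()], [read_biosamples()] or [read_stomachs()].
#'
#' @param x a table read by one of the `read_*` functions.
#' @return list with `n_read`, `n_accepted`, `n_rejected` and `violations`
#'   (named integer tally per rule).
#' @export
io_report <- function(x) attr(x, "io_report")

read_raw <- function(path, dialect) {
  tn_assert(file.exists(path), sprintf("file not found: %s", path),
            "tn_input_error")
  utils::read.table(path, header = TRUE, sep = dialect$sep,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "")
}

require_cols <- function(raw, cols) {
  missing <- setdiff(cols, names(raw))
  tn_assert(length(missing) == 0,
            sprintf("missing required column(s): %s",
                    paste(missing, collapse = ", ")),
            "tn_schema_error")
}

parse_num <- function(x, na_token) {
  x[x == "" | x == na_token | is.na(x)] <- NA_character_
  suppressWarnings(as.numeric(x))
}

attach_report <- function(df, n_read, violations) {
  rownames(df) <- NULL
  attr(df, "io_report") <- list(
    n_read = n_read,
    n_accepted = nrow(df),
    n_rejected = n_read - nrow(df),
    violations = violations
  )
  df
}

# Shared row-rejection bookkeeping: `rules` is a named list of logical
# "bad row" vectors, evaluated in order; the first rule that fires claims
# the row.
reject_rows <- function(n, rules) {
  bad <- rep(FALSE, n)
  tally <- integer(0)
  for (rule in names(rules)) {
    hit <- rules[[rule]] & !bad
    tally[rule] <- sum(hit)
    bad <- bad | hit
  }
  list(bad = bad, tally = tally[tally > 0])
}

#' Read a station table
#'
#' One row per tow. Required columns: `station_id`, `survey` (`spring` /
#' `autumn`), `year`, `latitude`, `longitude` (decimal degrees,
#' west-negative), `depth` (m), `bottom_temp` (degrees C, may be missing),
#' `catch_count`. Rows with a logically impossible value (nonpositive or
#' non-numeric depth, negative or non-integer catch, unknown season label,
#' temperature outside the plausibility window) are rejected and tallied
#' in the attached [io_report()]; an absent temperature is parsed as
#' missing, never as zero.
#'
#' @param path file path.
#' @param dialect an [io_dialect()].
#' @param temp_window plausibility window for present temperatures,
#'   degrees C.
#' @return data frame of stations, row order preserved, with an
#'   [io_report()] attribute.
#' @export
read_stations <- function(path, dialect = io_dialect(),
                          temp_window = c(-2, 30)) {
  raw <- read_raw(path, dialect)
  require_cols(raw, c("station_id", "survey", "year", "latitude",
                      "longitude", "depth", "bottom_temp", "catch_count"))
  df <- data.frame(
    station_id = raw$station_id,
    survey = raw$survey,
    year = parse_num(raw$year, dialect$na),
    latitude = parse_num(raw$latitude, dialect$na),
    longitude = parse_num(raw$longitude, dialect$na),
    depth = parse_num(raw$depth, dialect$na),
    bottom_temp = parse_num(raw$bottom_temp, dialect$na),
    catch_count = parse_num(raw$catch_count, dialect$na),
    stringsAsFactors = FALSE
  )
  rej <- reject_rows(nrow(df), list(
    bad_survey = !(df$survey %in% c("spring", "autumn")),
    bad_depth = is.na(df$depth) | df$depth <= 0,
    bad_catch = is.na(df$catch_count) | df$catch_count < 0 |
      df$catch_count != round(df$catch_count),
    bad_year = is.na(df$year),
    implausible_temp = !is.na(df$bottom_temp) &
      (df$bottom_temp < temp_window[1] | df$bottom_temp > temp_window[2])
  ))
  out <- df[!rej$bad, , drop = FALSE]
  out$year <- as.integer(out$year)
  out$catch_count <- as.integer(out$catch_count)
  attach_report(out, nrow(df), rej$tally)
}

#' Read a specimen table
#'
#' One row per measured individual. Required columns: `station_id`, `sex`,
#' `total_length` (cm), `weight` (g, optional per row), `maturity_stage`
#' (1-7, optional per row). Sex codes are mapped through the dialect's
#' code table (default `M`/`F`/`U`). Rows with an unknown sex code, a
#' nonpositive length or weight, or a stage outside 1-7 are rejected and
#' tallied. Station references are NOT resolved here; see
#' [validate_dataset()].
#'
#' @inheritParams read_stations
#' @return data frame of specimens with an [io_report()] attribute.
#' @export
read_biosamples <- function(path, dialect = io_dialect()) {
  raw <- read_raw(path, dialect)
  require_cols(raw, c("station_id", "sex", "total_length", "weight",
                      "maturity_stage"))
  sex_raw <- raw$sex
  sex <- unname(dialect$sex_codes[sex_raw])
  # allow already-decoded labels too
  decoded <- sex_raw %in% c("male", "female", "unknown")
  sex[decoded] <- sex_raw[decoded]
  df <- data.frame(
    station_id = raw$station_id,
    sex = sex,
    total_length = parse_num(raw$total_length, dialect$na),
    weight = parse_num(raw$weight, dialect$na),
    maturity_stage = parse_num(raw$maturity_stage, dialect$na),
    stringsAsFactors = FALSE
  )
  rej <- reject_rows(nrow(df), list(
    unknown_sex_code = is.na(df$sex),
    bad_length = is.na(df$total_length) | df$total_length <= 0,
    bad_weight = !is.na(df$weight) & df$weight <= 0,
    stage_out_of_range = !is.na(df$maturity_stage) &
      (df$maturity_stage < 1 | df$maturity_stage > 7 |
         df$maturity_stage != round(df$maturity_stage))
  ))
  out <- df[!rej$bad, , drop = FALSE]
  out$maturity_stage <- as.integer(out$maturity_stage)
  attach_report(out, nrow(df), rej$tally)
}

#' Read a stomach table
#'
#' One row per examined stomach. Required columns: `station_id`,
#' `is_empty` (TRUE/FALSE), and one content-weight column (g) per prey
#' category: `teleost`, `crustacean`, `cephalopod`, `echinoderm`,
#' `unidentified` (zero when absent). Rows violating the emptiness
#' invariant (an empty stomach with positive content mass) or with a
#' negative weight are rejected.
#'
#' @inheritParams read_stations
#' @return data frame of stomach records with an [io_report()] attribute.
#' @export
read_stomachs <- function(path, dialect = io_dialect()) {
  raw <- read_raw(path, dialect)
  require_cols(raw, c("station_id", "is_empty", PREY_CATEGORIES))
  df <- data.frame(station_id = raw$station_id,
                   is_empty = as.logical(raw$is_empty),
                   stringsAsFactors = FALSE)
  for (k in PREY_CATEGORIES) df[[k]] <- parse_num(raw[[k]], dialect$na)
  wmat <- as.matrix(df[, PREY_CATEGORIES, drop = FALSE])
  rej <- reject_rows(nrow(df), list(
    bad_empty_flag = is.na(df$is_empty),
    negative_weight = apply(wmat, 1, function(r) any(is.na(r) | r < 0)),
    nonzero_empty = df$is_empty & rowSums(wmat) > 0
  ))
  attach_report(df[!rej$bad, , drop = FALSE], nrow(df), rej$tally)
}

#' Cross-validate the three survey tables
#'
#' Pure consistency check across the parsed tables: every specimen and
#' stomach must reference an existing station; duplicate station ids are
#' flagged; depth or temperature outside the survey's observed extremes
#' (defaults 18-1359 m and -1 to 11 degrees C) raise range WARNINGS, not
#' rejections, since those windows describe past observations rather than
#' physical limits. All findings are reported; the caller decides the
#' severity policy.
#'
#' @param stations,samples,stomachs parsed tables ( `stomachs` may be
#'   `NULL`).
#' @param depth_window,temp_window observed-range windows for warnings.
#' @return object of class `"validation_report"`: list with `n_stations`,
#'   `n_samples`, `n_stomachs`, `violations` (named tally of errors),
#'   `warnings` (named tally), and `worst` (`"ok"`, `"warning"` or
#'   `"error"`).
#' @export
validate_dataset <- function(stations, samples, stomachs = NULL,
                             depth_window = c(18, 1359),
                             temp_window = c(-1, 11)) {
  viol <- integer(0)
  warn <- integer(0)
  dup <- sum(duplicated(stations$station_id))
  if (dup > 0) viol["duplicate_station_id"] <- dup
  bad_ref <- sum(!(samples$station_id %in% stations$station_id))
  if (bad_ref > 0) viol["unresolved_sample_station"] <- bad_ref
  if (!is.null(stomachs)) {
    bad_sto <- sum(!(stomachs$station_id %in% stations$station_id))
    if (bad_sto > 0) viol["unresolved_stomach_station"] <- bad_sto
  }
  out_depth <- sum(stations$depth < depth_window[1] |
                     stations$depth > depth_window[2])
  if (out_depth > 0) warn["depth_outside_observed_range"] <- out_depth
  out_temp <- sum(!is.na(stations$bottom_temp) &
                    (stations$bottom_temp < temp_window[1] |
                       stations$bottom_temp > temp_window[2]))
  if (out_temp > 0) warn["temp_outside_observed_range"] <- out_temp
  out <- list(
    n_stations = nrow(stations),
    n_samples = nrow(samples),
    n_stomachs = if (is.null(stomachs)) 0L else nrow(stomachs),
    violations = viol,
    warnings = warn,
    worst = if (length(viol) > 0) "error"
            else if (length(warn) > 0) "warning" else "ok"
  )
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: %d stations, %d specimens, %d stomachs -- %s\n",
              x$n_stations, x$n_samples, x$n_stomachs, toupper(x$worst)))
  for (k in names(x$violations))
    cat(sprintf("  violation %s: %d\n", k, x$violations[k]))
  for (k in names(x$warnings))
    cat(sprintf("  warning   %s: %d\n", k, x$warnings[k]))
  invisible(x)
}

#' Write a survey or result table
#'
#' Writes any of the package's tables as delimited text under the given
#' dialect; missing values become the dialect's missing token, so
#' `read_*(write_table(x))` round-trips field-for-field.
#'
#' @param records data frame.
#' @param path output path.
#' @param dialect an [io_dialect()].
#' @export
write_table <- function(records, path, dialect = io_dialect()) {
  dir <- dirname(path)
  tn_assert(dir.exists(dir), sprintf("directory does not exist: %s", dir),
            "tn_output_error")
  utils::write.table(records, path, sep = dialect$sep, na = dialect$na,
                     row.names = FALSE, quote = TRUE)
}
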