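# Catch-weighted niche statistics over the station table.
#
# All functions here take the station data frame produced by read_stations()
# or generate_survey(): columns station_id, survey, year, latitude,
# longitude, depth, bottom_temp, catch_count. Stations with a missing value
# of the analysed variable are excluded from BOTH weighted and unweighted
# statistics (never imputed); the number excluded is reported where the
# return type carries provenance.

niche_var <- function(stations, variable) {
  tn_assert(variable %in% c("temperature", "depth"),
            sprintf("unknown variable '%s' (use 'temperature' or 'depth')",
                    variable),
            "tn_config_error")
  if (variable == "temperature") stations$bottom_temp else stations$depth
}

filter_season <- function(stations, season) {
  tn_assert(season %in% c("both", "spring", "autumn"),
            "season must be 'both', 'spring' or 'autumn'", "tn_config_error")
  if (season == "both") stations else stations[stations$survey == season, , drop = FALSE]
}

#' Thermal bias of a species from survey catches
#'
#' The thermal bias (TB) is the median bottom temperature of all surveyed
#' stations subtracted from the median catch-weighted temperature: the
#' weighted median uses each station's catch count as its weight, while the
#' unweighted median is taken over every station with a valid temperature,
#' including zero-catch tows. A positive TB classifies the species as
#' warmwater (it concentrates in tows warmer than the typical station), a
#' negative TB as coldwater.
#'
#' @param stations station data frame (columns `bottom_temp`, `catch_count`,
#'   `survey`).
#' @param season `"both"` (default; the index pools both seasonal surveys
#'   across all years), `"spring"` or `"autumn"`.
#' @return thermal bias in degrees C.
#' @export
thermal_bias <- function(stations, season = "both") {
  stations <- filter_season(stations, season)
  ok <- !is.na(stations$bottom_temp)
  tn_assert(any(ok), "no stations with a valid temperature",
            "tn_missing_data_error")
  temps <- stations$bottom_temp[ok]
  catch <- stations$catch_count[ok]
  tn_assert(sum(catch) > 0,
            "zero total catch among temperature-valid stations",
            "tn_no_catch_error")
  weighted_quantile(temps, catch, 0.5) -
    weighted_quantile(temps, rep(1, length(temps)), 0.5)
}

#' Stenothermality index
#'
#' Width of the central 90% of the catch-weighted temperature distribution:
#' the difference between the 95th and 5th percentiles of station
#' temperatures weighted by catch count. A small value indicates a
#' stenothermal species (narrow thermal tolerance), a large one a
#' eurythermal species.
#'
#' @inheritParams thermal_bias
#' @param probs percentile pair delimiting the range; default `c(0.05, 0.95)`.
#' @return temperature range in degrees C (nonnegative).
#' @export
steno_index <- function(stations, season = "both", probs = c(0.05, 0.95)) {
  stations <- filter_season(stations, season)
  ok <- !is.na(stations$bottom_temp)
  tn_assert(any(ok), "no stations with a valid temperature",
            "tn_missing_data_error")
  temps <- stations$bottom_temp[ok]
  catch <- stations$catch_count[ok]
  tn_assert(sum(catch) > 0,
            "zero total catch among temperature-valid stations",
            "tn_no_catch_error")
  q <- weighted_quantile(temps, catch, sort(probs))
  q[2] - q[1]
}

#' Occupancy interval for temperature or depth
#'
#' The range of a habitat variable delimited by a percentile pair of either
#' the catch-weighted distribution (where the individuals were caught) or
#' the unweighted station distribution (what the survey sampled). The
#' default pair `(0.05, 0.95)` spans the central 90%.
#'
#' @inheritParams thermal_bias
#' @param variable `"temperature"` or `"depth"`.
#' @param probs increasing percentile pair in `[0, 1]`.
#' @param weighted if `TRUE` (default) weight stations by catch count;
#'   if `FALSE` use unit station weights.
#' @return named numeric vector `c(lo, hi)`.
#' @export
occupancy_interval <- function(stations, variable = "temperature",
                               probs = c(0.05, 0.95), weighted = TRUE,
                               season = "both") {
  tn_assert(length(probs) == 2 && probs[1] < probs[2],
            "probs must be an increasing pair", "tn_config_error")
  stations <- filter_season(stations, season)
  x <- niche_var(stations, variable)
  ok <- !is.na(x)
  tn_assert(any(ok), sprintf("no stations with valid %s", variable),
            "tn_missing_data_error")
  w <- if (weighted) stations$catch_count[ok] else rep(1, sum(ok))
  q <- weighted_quantile(x[ok], w, probs)
  c(lo = q[1], hi = q[2])
}

#' Width of an occupancy interval
#'
#' @param interval numeric pair `c(lo, hi)` with `lo <= hi`, as returned by
#'   [occupancy_interval()].
#' @return `hi - lo`, in the interval's units.
#' @export
interval_width <- function(interval) {
  tn_assert(length(interval) == 2 && !anyNA(interval),
            "interval must be a numeric pair", "tn_shape_error")
  tn_assert(interval[1] <= interval[2], "interval is inverted (lo > hi)",
            "tn_invariant_error")
  unname(interval[2] - interval[1])
}

#' Compare mean habitat values between two seasons
#'
#' One-way ANOVA with two groups, e.g. the bottom temperatures of the
#' spring versus autumn tows that caught the species. With two groups the
#' F statistic equals the square of the pooled-variance two-sample
#' t statistic.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @return list with `statistic` (F), `p_value`, and `df` (pair `c(1, n-2)`).
#' @export
seasonal_mean_compare <- function(values_a, values_b) {
  tn_assert(length(values_a) >= 2 && length(values_b) >= 2,
            "each group needs at least 2 values", "tn_insufficient_data_error")
  y <- c(values_a, values_b)
  g <- factor(rep(c("a", "b"), c(length(values_a), length(values_b))))
  tab <- stats::anova(stats::lm(y ~ g))
  list(statistic = unname(tab[["F value"]][1]),
       p_value = unname(tab[["Pr(>F)"]][1]),
       df = c(tab$Df[1], tab$Df[2]))
}

#' Niche summary for one habitat variable
#'
#' Bundles the catch-weighted niche statistics for temperature or depth:
#' thermal bias (temperature only), the Steno index (width of the central
#' 90% of the catch-weighted distribution), the weighted and unweighted
#' occupancy intervals, and provenance counts (stations used, stations
#' excluded for missing values, total catch weight).
#'
#' @inheritParams occupancy_interval
#' @return object of class `"niche_summary"`: a list with elements
#'   `variable`, `season`, `tb`, `steno`, `interval` (weighted),
#'   `interval_unweighted`, `probs`, `n_stations`, `n_missing`,
#'   `total_catch`.
#' @export
niche_summary <- function(stations, variable = "temperature",
                          probs = c(0.05, 0.95), season = "both") {
  scoped <- filter_season(stations, season)
  x <- niche_var(scoped, variable)
  ok <- !is.na(x)
  tn_assert(any(ok), sprintf("no stations with valid %s", variable),
            "tn_missing_data_error")
  tn_assert(sum(scoped$catch_count[ok]) > 0,
            "zero total catch among valid stations", "tn_no_catch_error")
  out <- list(
    variable = variable,
    season = season,
    tb = if (variable == "temperature") thermal_bias(scoped) else NA_real_,
    steno = steno_index_of(x[ok], scoped$catch_count[ok], probs),
    interval = occupancy_interval(scoped, variable, probs, weighted = TRUE),
    interval_unweighted = occupancy_interval(scoped, variable, probs,
                                             weighted = FALSE),
    probs = probs,
    n_stations = sum(ok),
    n_missing = sum(!ok),
    total_catch = sum(scoped$catch_count[ok])
  )
  class(out) <- "niche_summary"
  out
}

# Steno index on raw vectors (shared by niche_summary for depth, where the
# same 5th-95th width of the weighted distribution is a depth range).
steno_index_of <- function(x, w, probs = c(0.05, 0.95)) {
  q <- weighted_quantile(x, w, sort(probs))
  q[2] - q[1]
}

#' @export
print.niche_summary <- function(x, ...) {
  unit <- if (x$variable == "temperature") "degC" else "m"
  cat(sprintf("Catch-weighted niche summary: %s (%s surveys)\n",
              x$variable, x$season))
  if (!is.na(x$tb))
    cat(sprintf("  thermal bias: %.2f degC (%s-water)\n", x$tb,
                if (x$tb >= 0) "warm" else "cold"))
  cat(sprintf("  central %d%% width (Steno): %.2f %s\n",
              round(100 * diff(x$probs)), x$steno, unit))
  cat(sprintf("  weighted   %g-%g%% interval: [%.1f, %.1f] %s\n",
              100 * x$probs[1], 100 * x$probs[2],
              x$interval[1], x$interval[2], unit))
  cat(sprintf("  unweighted %g-%g%% interval: [%.1f, %.1f] %s\n",
              100 * x$probs[1], 100 * x$probs[2],
              x$interval_unweighted[1], x$interval_unweighted[2], unit))
  cat(sprintf("  stations used: %d (excluded for missing %s: %d), total catch %g\n",
              x$n_stations, x$variable, x$n_missing, x$total_catch))
  invisible(x)
}
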