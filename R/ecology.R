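# Diet composition, subgroup habitat envelopes, and the annual
# catch-per-tow abundance index.

PREY_CATEGORIES <- c("teleost", "crustacean", "cephalopod", "echinoderm",
                     "unidentified")

#' Stomach-content summary
#'
#' Vacuity (percentage of all examined stomachs that are empty), per-prey
#' frequency of occurrence (percentage of NON-empty stomachs containing the
#' category — occurrence percentages can therefore sum to more than 100
#' when prey co-occur), and weight percentage (percentage of the total
#' content mass contributed by the category).
#'
#' @param stomachs stomach data frame: columns `is_empty` (logical) and one
#'   numeric weight column (g) per prey category (`teleost`, `crustacean`,
#'   `cephalopod`, `echinoderm`, `unidentified`).
#' @return object of class `"diet_summary"`: list with `n_stomachs`,
#'   `n_empty`, `vacuity` (%), `occurrence` (named %, `NA` if no non-empty
#'   stomachs), `weight_pct` (named %, `NA` likewise).
#' @export
diet_summary <- function(stomachs) {
  tn_assert(nrow(stomachs) >= 1, "no stomachs to summarise",
            "tn_insufficient_data_error")
  tn_assert(all(PREY_CATEGORIES %in% names(stomachs)),
            "stomach table is missing a prey-category column",
            "tn_schema_error")
  n <- nrow(stomachs)
  n_empty <- sum(stomachs$is_empty)
  nonempty <- stomachs[!stomachs$is_empty, , drop = FALSE]
  wmat <- as.matrix(stomachs[, PREY_CATEGORIES, drop = FALSE])
  total_mass <- sum(wmat)
  if (nrow(nonempty) == 0) {
    occ <- wpct <- stats::setNames(rep(NA_real_, length(PREY_CATEGORIES)),
                                   PREY_CATEGORIES)
  } else {
    nm <- as.matrix(nonempty[, PREY_CATEGORIES, drop = FALSE])
    occ <- 100 * colSums(nm > 0) / nrow(nonempty)
    wpct <- if (total_mass > 0) 100 * colSums(wmat) / total_mass
            else stats::setNames(rep(NA_real_, length(PREY_CATEGORIES)),
                                 PREY_CATEGORIES)
  }
  out <- list(n_stomachs = n, n_empty = n_empty,
              vacuity = 100 * n_empty / n,
              occurrence = occ, weight_pct = wpct)
  class(out) <- "diet_summary"
  out
}

#' @export
print.diet_summary <- function(x, ...) {
  cat(sprintf("Diet summary: %d stomachs, vacuity %.1f%% (%d empty)\n",
              x$n_stomachs, x$vacuity, x$n_empty))
  if (!anyNA(x$occurrence)) {
    ord <- order(x$occurrence, decreasing = TRUE)
    for (k in names(x$occurrence)[ord])
      cat(sprintf("  %-12s %%O = %5.1f   %%W = %5.1f\n",
                  k, x$occurrence[k], x$weight_pct[k]))
  }
  invisible(x)
}

#' Habitat envelope of a subgroup of individuals
#'
#' Environmental envelope (depth, temperature, position) of the stations at
#' which a selected subgroup of individuals was caught, e.g. juveniles
#' (TL <= 20 cm) or late-stage pregnant females. Aggregation is at the
#' individual level: a station contributing k selected individuals enters
#' the mean k times, because the reported ranges and means describe the
#' individuals caught, not the tows. Individuals at stations with a missing
#' temperature are excluded from the temperature statistics only, with the
#' count reported.
#'
#' @param stations station data frame.
#' @param samples specimen data frame (columns `station_id`, `sex`,
#'   `total_length`, `weight`, `maturity_stage`).
#' @param predicate function taking the specimen data frame and returning a
#'   logical selection vector (e.g. `function(s) s$total_length <= 20`).
#' @param label name for the subgroup carried in the summary.
#' @return object of class `"envelope_summary"`: list with `label`, `n`,
#'   `depth` and `temperature` (each `c(min, mean, max)`),
#'   `n_missing_temp`, `lat_range`, `lon_range`.
#' @export
subgroup_envelope <- function(stations, samples, predicate,
                              label = "subgroup") {
  sel <- predicate(samples)
  sel[is.na(sel)] <- FALSE
  tn_assert(any(sel), "predicate selects no individuals",
            "tn_empty_subgroup_error")
  chosen <- samples[sel, , drop = FALSE]
  idx <- match(chosen$station_id, stations$station_id)
  tn_assert(!anyNA(idx),
            "selected individuals reference unknown stations",
            "tn_crossref_error")
  st <- stations[idx, , drop = FALSE]
  mmm <- function(v) c(min = min(v), mean = mean(v), max = max(v))
  tok <- !is.na(st$bottom_temp)
  out <- list(
    label = label,
    n = nrow(chosen),
    depth = mmm(st$depth),
    temperature = if (any(tok)) mmm(st$bottom_temp[tok])
                  else c(min = NA_real_, mean = NA_real_, max = NA_real_),
    n_missing_temp = sum(!tok),
    lat_range = range(st$latitude),
    lon_range = range(st$longitude)
  )
  class(out) <- "envelope_summary"
  out
}

#' @export
print.envelope_summary <- function(x, ...) {
  cat(sprintf("Habitat envelope: %s (n = %d)\n", x$label, x$n))
  cat(sprintf("  depth: %.0f-%.0f m (mean %.0f m)\n",
              x$depth["min"], x$depth["max"], x$depth["mean"]))
  if (!anyNA(x$temperature))
    cat(sprintf("  temperature: %.1f-%.1f degC (mean %.1f degC)\n",
                x$temperature["min"], x$temperature["max"],
                x$temperature["mean"]))
  invisible(x)
}

#' Overlap of two habitat envelopes
#'
#' Per-variable interval intersection of two subgroup envelopes,
#' `[max(min_a, min_b), min(max_a, max_b)]` — the construction behind a
#' critical-habitat delineation as the depth/temperature window shared by
#' late-stage pregnant females and small juveniles. An empty intersection
#' is reported as disjoint, not as an error.
#'
#' @param a,b [subgroup_envelope()] results.
#' @param variables which variables to intersect; any of `"depth"`,
#'   `"temperature"`.
#' @return named list per variable: either `c(lo, hi)` or `NULL` with
#'   attribute `disjoint = TRUE` recorded in the `disjoint` element.
#' @export
envelope_overlap <- function(a, b, variables = c("depth", "temperature")) {
  res <- list()
  for (v in variables) {
    tn_assert(!is.null(a[[v]]) && !is.null(b[[v]]) &&
                !anyNA(a[[v]]) && !anyNA(b[[v]]),
              sprintf("variable '%s' undefined in an envelope", v),
              "tn_undefined_variable_error")
    lo <- max(a[[v]]["min"], b[[v]]["min"])
    hi <- min(a[[v]]["max"], b[[v]]["max"])
    res[[v]] <- if (lo <= hi) c(lo = unname(lo), hi = unname(hi)) else NULL
  }
  res$disjoint <- vapply(variables, function(v) is.null(res[[v]]), logical(1))
  res
}

#' Annual catch-per-tow abundance index
#'
#' For each (year, season) cell: number of tows fished, total catch, and
#' mean catch per tow with zero-catch tows included — the survey index of
#' relative abundance. Optionally fits an ordinary least-squares trend of
#' the index on year (season-year cells as observations) with a 95%
#' confidence interval on the slope.
#'
#' @param stations station data frame.
#' @param trend fit a linear trend of mean catch per tow on year.
#' @return data frame of class `"abundance_series"` with columns `year`,
#'   `survey`, `n_tows`, `total_catch`, `mean_catch`; if `trend`, an
#'   attribute `trend` holding `slope`, `ci` (95%), `se`, `p_value`.
#' @export
annual_abundance_index <- function(stations, trend = TRUE) {
  tn_assert(nrow(stations) >= 1, "no stations", "tn_insufficient_data_error")
  agg <- stats::aggregate(
    catch_count ~ year + survey, data = stations,
    FUN = function(v) c(n = length(v), tot = sum(v), mean = mean(v))
  )
  out <- data.frame(
    year = agg$year,
    survey = agg$survey,
    n_tows = agg$catch_count[, "n"],
    total_catch = agg$catch_count[, "tot"],
    mean_catch = agg$catch_count[, "mean"]
  )
  out <- out[order(out$year, out$survey), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("abundance_series", "data.frame")
  if (trend && length(unique(out$year)) >= 3) {
    fit <- stats::lm(mean_catch ~ year, data = out)
    ci <- stats::confint(fit, "year", level = 0.95)
    attr(out, "trend") <- list(
      slope = unname(stats::coef(fit)["year"]),
      ci = c(lo = ci[1], hi = ci[2]),
      se = summary(fit)$coefficients["year", "Std. Error"],
      p_value = summary(fit)$coefficients["year", "Pr(>|t|)"]
    )
  }
  out
}
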