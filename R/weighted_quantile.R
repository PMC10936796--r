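#' Catch-weighted sample quantiles
#'
#' Quantiles of a set of measurements in which each value carries a
#' nonnegative weight — here, station-level temperatures or depths weighted
#' by the number of target-species individuals caught at the station. For
#' integer weights the estimate equals the linear-interpolation sample
#' quantile (type 7) of the expanded per-individual vector in which each
#' value is repeated `weight` times, which is the natural estimand when the
#' quantity of interest is "the temperature experienced by X% of the
#' individuals". Fractional weights are handled by interpolating the
#' cumulative-weight position `h = (W - 1) * p + 1`, where `W` is the total
#' weight.
#'
#' @param values numeric vector of measurements (e.g. bottom temperature in
#'   degrees C, or tow depth in m).
#' @param weights nonnegative numeric weights, same length as `values`;
#'   at least one must be strictly positive. Zero-weight values never
#'   influence the result.
#' @param p probabilities in `[0, 1]` (may be a vector).
#' @param na.rm drop `NA` values (and their weights) before computing.
#' @return numeric vector of quantiles, one per element of `p`.
#' @examples
#' weighted_quantile(c(10, 20), c(3, 1), 0.75)  # 12.5
#' @export
weighted_quantile <- function(values, weights, p, na.rm = FALSE) {
  tn_assert(length(values) == length(weights),
            "values and weights must have the same length", "tn_shape_error")
  tn_assert(all(p >= 0 & p <= 1), "p must lie in [0, 1]", "tn_config_error")
  if (na.rm) {
    keep <- !is.na(values) & !is.na(weights)
    values <- values[keep]; weights <- weights[keep]
  }
  tn_assert(!anyNA(values) && !anyNA(weights),
            "missing values present (use na.rm = TRUE)", "tn_missing_data_error")
  tn_assert(all(weights >= 0), "weights must be nonnegative", "tn_domain_error")
  keep <- weights > 0
  values <- values[keep]; weights <- weights[keep]
  W <- sum(weights)
  tn_assert(length(values) > 0 && W > 0,
            "all weights are zero: weighted quantile undefined",
            "tn_degenerate_weight_error")

  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord])

  # value at cumulative position k in (0, W]: the i with cw[i-1] < k <= cw[i]
  pos <- function(k) {
    k <- pmin(pmax(k, 1e-12), W)
    idx <- findInterval(k, cw, left.open = TRUE) + 1L
    v[pmin(idx, length(v))]
  }

  h <- (W - 1) * p + 1
  k1 <- floor(h)
  g <- h - k1
  lo <- pos(pmax(k1, 1))
  hi <- pos(pmin(k1 + 1, W))
  unname(lo + g * (hi - lo))
}

#' Weighted empirical cumulative distribution function
#'
#' Builds the right-continuous step function `F(x) =` (total weight of
#' observations with value `<= x`) / (total weight). With unit weights this
#' is the ordinary empirical CDF of the station values; with catch weights
#' it is the CDF of the values experienced by the individuals caught.
#' Comparing the two reveals whether enhanced catches are associated with a
#' particular range of temperature or depth.
#'
#' @inheritParams weighted_quantile
#' @return a function of class `"weighted_ecdf"` mapping values to
#'   cumulative probabilities, with attributes `support` (sorted unique
#'   values) and `cum` (cumulative normalised weights, ending at 1).
#' @seealso [weighted_quantile()], [occupancy_interval()]
#' @export
weighted_ecdf <- function(values, weights = rep(1, length(values)),
                          na.rm = FALSE) {
  tn_assert(length(values) == length(weights),
            "values and weights must have the same length", "tn_shape_error")
  if (na.rm) {
    keep <- !is.na(values) & !is.na(weights)
    values <- values[keep]; weights <- weights[keep]
  }
  tn_assert(!anyNA(values) && !anyNA(weights),
            "missing values present (use na.rm = TRUE)", "tn_missing_data_error")
  tn_assert(all(weights >= 0), "weights must be nonnegative", "tn_domain_error")
  keep <- weights > 0
  values <- values[keep]; weights <- weights[keep]
  tn_assert(length(values) > 0,
            "all weights are zero: ECDF undefined", "tn_degenerate_weight_error")

  w <- vapply(split(weights, factor(values, levels = sort(unique(values)))),
              sum, numeric(1))
  support <- sort(unique(values))
  cum <- cumsum(w) / sum(w)

  f <- function(q) {
    idx <- findInterval(q, support)
    ifelse(idx == 0, 0, cum[pmax(idx, 1)])
  }
  attr(f, "support") <- support
  attr(f, "cum") <- unname(cum)
  class(f) <- c("weighted_ecdf", "function")
  f
}

#' @export
print.weighted_ecdf <- function(x, ...) {
  s <- attr(x, "support")
  cat("Weighted ECDF on", length(s), "support points,",
      "range [", format(min(s)), ",", format(max(s)), "]\n")
  invisible(x)
}

#' Tabulate a weighted ECDF
#'
#' @param x a [weighted_ecdf()] object.
#' @return data frame with columns `value` and `cum_weight`.
#' @export
as.data.frame.weighted_ecdf <- function(x, ...) {
  data.frame(value = attr(x, "support"), cum_weight = attr(x, "cum"))
}
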