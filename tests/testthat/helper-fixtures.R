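# Shared fixtures: tiny station tables built in code, and the standard
# synthetic-survey configuration used by the closed-form checks.

make_stations <- function(temps, catches, depth = NULL, survey = "autumn",
                          year = 2020) {
  n <- length(temps)
  data.frame(
    station_id = sprintf("st-%03d", seq_len(n)),
    survey = rep_len(survey, n),
    year = rep_len(year, n),
    latitude = rep(64, n),
    longitude = rep(-20, n),
    depth = if (is.null(depth)) rep(400, n) else rep_len(depth, n),
    bottom_temp = temps,
    catch_count = as.integer(catches),
    stringsAsFactors = FALSE
  )
}

# Stenothermal-survey configuration under which the catch-weighted
# temperature distribution has the closed form Normal(7.150, 0.6352):
# thermal bias 1.46 and Steno index 2.09.
steno_config <- function(n_per_season = 20000) {
  generator_config(n_stations = c(spring = n_per_season,
                                  autumn = n_per_season))
}

# Simulate one maturity dataset from the generating ogive
# (beta0 = -12.5, beta1 = 0.25, i.e. L50 = 50 cm), lengths uniform 13-66.
simulate_maturity <- function(n, beta0 = -12.5, beta1 = 0.25) {
  tl <- stats::runif(n, 13, 66)
  list(length = tl,
       mature = stats::runif(n) < stats::plogis(beta0 + beta1 * tl))
}
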