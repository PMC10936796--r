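# Diet summaries, subgroup habitat envelopes and the abundance index.

make_stomachs <- function(n_empty, teleost = integer(0),
                          crustacean = integer(0)) {
  n <- n_empty + max(length(teleost), length(crustacean), 0)
  df <- data.frame(
    station_id = sprintf("s-%02d", seq_len(n)),
    is_empty = c(rep(TRUE, n_empty), rep(FALSE, n - n_empty)),
    teleost = rep(0, n), crustacean = rep(0, n), cephalopod = rep(0, n),
    echinoderm = rep(0, n), unidentified = rep(0, n),
    stringsAsFactors = FALSE)
  if (length(teleost)) df$teleost[(n_empty + 1):n] <- teleost
  if (length(crustacean)) df$crustacean[(n_empty + 1):n] <- crustacean
  df
}

test_that("diet summary computes vacuity, occurrence and weight percentages", {
  # 27 stomachs, 5 empty: vacuity 100*5/27; teleost in 11 of 22 non-empty
  sto <- make_stomachs(5, teleost = c(rep(10, 11), rep(0, 11)),
                       crustacean = c(rep(0, 11), rep(5, 11)))
  d <- diet_summary(sto)
  expect_equal(d$n_stomachs, 27)
  expect_equal(d$vacuity, 100 * 5 / 27)
  expect_equal(unname(d$occurrence["teleost"]), 50)
  expect_equal(unname(d$occurrence["crustacean"]), 50)
  expect_equal(unname(d$weight_pct["teleost"]), 100 * 110 / 165)
  # weight percentages partition the mass
  expect_equal(sum(d$weight_pct), 100, tolerance = 0.1)
  # occurrence can exceed 100 in total under co-occurrence
  both <- make_stomachs(0, teleost = rep(4, 6), crustacean = rep(2, 6))
  db <- diet_summary(both)
  expect_equal(sum(db$occurrence), 200)
})

test_that("diet edge cases: single-prey stomach, all-empty, empty collection", {
  one <- make_stomachs(0, crustacean = 7)
  d <- diet_summary(one)
  expect_equal(unname(d$weight_pct["crustacean"]), 100)
  expect_equal(d$vacuity, 0)
  alle <- make_stomachs(4)
  da <- diet_summary(alle)
  expect_equal(da$vacuity, 100)
  expect_true(all(is.na(da$occurrence)))
  expect_true(all(is.na(da$weight_pct)))
  expect_error(diet_summary(make_stomachs(0)[0, ]),
               class = "tn_insufficient_data_error")
})

test_that("subgroup envelopes aggregate at the individual level", {
  st <- make_stations(c(7, 8, NA), c(5, 5, 5), depth = c(200, 600, 400))
  samples <- data.frame(
    station_id = c("st-001", "st-002", "st-001", "st-003"),
    sex = c("female", "female", "male", "female"),
    total_length = c(15, 18, 45, 12),
    weight = NA_real_, maturity_stage = NA_integer_,
    stringsAsFactors = FALSE)
  # one individual: min = mean = max
  e1 <- subgroup_envelope(st, samples, function(s) s$total_length == 45)
  expect_equal(unname(e1$depth), c(200, 200, 200))
  expect_equal(unname(e1$temperature), c(7, 7, 7))
  # juveniles at 200, 600 and 400 m; the 400 m station lacks temperature
  ej <- subgroup_envelope(st, samples, function(s) s$total_length <= 20,
                          label = "juveniles")
  expect_equal(ej$n, 3)
  expect_equal(unname(ej$depth), c(200, 400, 600))
  expect_equal(unname(ej$temperature), c(7, 7.5, 8))
  expect_equal(ej$n_missing_temp, 1)
  expect_error(subgroup_envelope(st, samples, function(s) s$total_length > 99),
               class = "tn_empty_subgroup_error")
})

test_that("envelopes match a brute-force join on synthetic data", {
  sv <- generate_survey(
    generator_config(n_stations = c(spring = 400, autumn = 400)), seed = 5)
  env <- subgroup_envelope(sv$stations, sv$samples,
                           function(s) s$total_length <= 20)
  joined <- merge(sv$samples[sv$samples$total_length <= 20, ],
                  sv$stations, by = "station_id")
  expect_equal(env$n, nrow(joined))
  expect_equal(unname(env$depth),
               c(min(joined$depth), mean(joined$depth), max(joined$depth)))
  expect_equal(unname(env$temperature["mean"]),
               mean(joined$bottom_temp, na.rm = TRUE))
  # containment: the envelope of a union contains each subgroup envelope
  env_all <- subgroup_envelope(sv$stations, sv$samples,
                               function(s) rep(TRUE, nrow(s)))
  expect_lte(env_all$depth["min"], env$depth["min"])
  expect_gte(env_all$depth["max"], env$depth["max"])
})

test_that("envelope overlap intersects intervals and reports disjointness", {
  mk <- function(dlo, dhi, tlo, thi) {
    structure(list(label = "x", n = 1,
                   depth = c(min = dlo, mean = (dlo + dhi) / 2, max = dhi),
                   temperature = c(min = tlo, mean = (tlo + thi) / 2,
                                   max = thi),
                   n_missing_temp = 0),
              class = "envelope_summary")
  }
  a <- mk(100, 500, 6, 8); b <- mk(300, 700, 7, 9)
  ov <- envelope_overlap(a, b)
  expect_equal(ov$depth, c(lo = 300, hi = 500))
  expect_equal(ov$temperature, c(lo = 7, hi = 8))
  expect_false(any(ov$disjoint))
  # disjoint depth ranges are reported, not raised
  ovd <- envelope_overlap(mk(100, 200, 6, 8), mk(300, 400, 6, 8))
  expect_null(ovd$depth)
  expect_true(ovd$disjoint[["depth"]])
  # idempotence
  ovi <- envelope_overlap(a, a)
  expect_equal(ovi$depth, c(lo = 100, hi = 500))
  # undefined variable
  na_env <- mk(100, 200, NA, NA)
  expect_error(envelope_overlap(a, na_env),
               class = "tn_undefined_variable_error")
})

test_that("abundance index is mean catch per tow with zero tows included", {
  st <- make_stations(c(6, 7, 8), c(0, 2, 4), year = 2015)
  ser <- annual_abundance_index(st, trend = FALSE)
  expect_equal(ser$mean_catch, 2)
  expect_equal(ser$n_tows, 3)
  expect_equal(ser$total_catch, 6)
  # identity: mean = total / n
  expect_equal(ser$mean_catch, ser$total_catch / ser$n_tows)
  # all-zero catches
  z <- annual_abundance_index(make_stations(c(6, 7), c(0, 0)), trend = FALSE)
  expect_equal(z$mean_catch, 0)
  # order invariance and batch-splitting invariance
  sv <- generate_survey(
    generator_config(n_stations = c(spring = 200, autumn = 200)), seed = 9)
  a <- annual_abundance_index(sv$stations)
  b <- annual_abundance_index(sv$stations[sample(nrow(sv$stations)), ])
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("a constant-rate survey shows no abundance trend", {
  cfg <- generator_config(n_stations = c(spring = 250, autumn = 250))
  covered <- vapply(1:100, function(s) {
    sv <- generate_survey(cfg, seed = 1000 + s)
    tr <- attr(annual_abundance_index(sv$stations), "trend")
    tr$ci[["lo"]] <= 0 && tr$ci[["hi"]] >= 0
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})
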