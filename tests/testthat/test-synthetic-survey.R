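# The synthetic survey generator: determinism, the station thermal field,
# the Poisson catch layer against its closed-form oracle, subsampling
# caps, and the stomach model.

test_that("the generator is deterministic record-for-record at a fixed seed", {
  cfg <- generator_config(n_stations = c(spring = 120, autumn = 120))
  a <- generate_survey(cfg, seed = 11)
  b <- generate_survey(cfg, seed = 11)
  expect_identical(a$stations, b$stations)
  expect_identical(a$samples, b$samples)
  expect_identical(a$stomachs, b$stomachs)
  c <- generate_survey(cfg, seed = 12)
  expect_false(identical(a$stations$bottom_temp, c$stations$bottom_temp))
})

test_that("station fields honour the configured ranges and the CLT bound", {
  cfg <- generator_config(n_stations = c(spring = 500, autumn = 500))
  st <- generate_stations(cfg, seed = 4)
  expect_equal(nrow(st), 1000)
  expect_equal(sort(unique(st$survey)), c("autumn", "spring"))
  sp <- st[st$survey == "spring", ]
  au <- st[st$survey == "autumn", ]
  expect_true(all(sp$depth >= 18 & sp$depth <= 550))
  expect_true(all(au$depth >= 23 & au$depth <= 1359))
  expect_true(all(st$year %in% 2010:2021))
  # independent thermal mode: sample mean within 3 sd/sqrt(n) of 5.69
  expect_lt(abs(mean(st$bottom_temp) - 5.69), 3 * 2.5 / sqrt(1000))
  # n = 0 gives an empty, well-formed table
  empty <- generate_stations(
    generator_config(n_stations = c(spring = 0, autumn = 0)), seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("station_id", "depth", "bottom_temp") %in% names(empty)))
})

test_that("catches are Poisson under the Gaussian thermal response", {
  cfg <- generator_config(n_stations = c(spring = 20000, autumn = 20000))
  st <- generate_catches(generate_stations(cfg, seed = 21), cfg, seed = 21)
  expect_true(all(st$catch_count >= 0))
  # empirical mean against the closed-form convolution, ~1.0586
  mu <- expected_mean_catch(cfg)
  expect_lt(abs(mean(st$catch_count) - mu), 0.04)
  # amplitude zero: no catches anywhere
  cfg0 <- generator_config(n_stations = c(spring = 50, autumn = 50),
                           catch_amplitude = 0)
  st0 <- generate_catches(generate_stations(cfg0, seed = 1), cfg0, seed = 1)
  expect_true(all(st0$catch_count == 0))
  expect_equal(expected_mean_catch(cfg0), 0)
  # missing temperature: catch 0 and flagged
  stm <- generate_stations(cfg0, seed = 2)
  stm$bottom_temp[1:5] <- NA
  stm <- generate_catches(stm, cfg0, seed = 2)
  expect_true(all(stm$catch_count[1:5] == 0))
  expect_equal(which(stm$catch_flagged), 1:5)
})

test_that("expected_mean_catch has the right limits and guards", {
  # flat response: the expectation approaches the amplitude
  flat <- generator_config(catch_center = 5.69, catch_sd = 1e6)
  expect_equal(expected_mean_catch(flat), 5, tolerance = 1e-6)
  dl <- generator_config(thermal_mode = "depth_linked")
  expect_error(expected_mean_catch(dl), class = "tn_unsupported_mode_error")
  # cross-check the closed form by numeric integration
  cfg <- generator_config()
  f <- function(t) cfg$catch_amplitude *
    exp(-(t - cfg$catch_center)^2 / (2 * cfg$catch_sd^2)) *
    stats::dnorm(t, cfg$temp_mean, cfg$temp_sd)
  expect_equal(expected_mean_catch(cfg),
               stats::integrate(f, -50, 50)$value, tolerance = 1e-8)
})

test_that("subsampling caps and per-station consistency hold for every station", {
  cfg <- generator_config(n_stations = c(spring = 300, autumn = 300))
  sv <- generate_survey(cfg, seed = 31)
  per_station <- table(factor(sv$samples$station_id,
                              levels = sv$stations$station_id))
  expect_true(all(per_station <= cfg$max_measured))
  expect_true(all(per_station <= sv$stations$catch_count))
  staged <- sv$samples[!is.na(sv$samples$maturity_stage), ]
  expect_true(all(table(staged$station_id) <= cfg$max_staged))
  # a single big station hits the caps exactly
  one <- make_stations(7.25, 50)
  ind <- generate_individuals(one, cfg, seed = 1)
  expect_equal(nrow(ind), 20)
  expect_equal(sum(!is.na(ind$maturity_stage)), 5)
  expect_equal(sum(!is.na(ind$weight)), 5)
})

test_that("individual biology follows the configured distributions", {
  cfg <- generator_config(n_stations = c(spring = 400, autumn = 400))
  sv <- generate_survey(cfg, seed = 41)
  s <- sv$samples
  f <- s[s$sex == "female", ]
  m <- s[s$sex == "male", ]
  expect_true(all(f$total_length >= 13 & f$total_length <= 66))
  expect_true(all(m$total_length >= 13 & m$total_length <= 62))
  expect_true(all(s$maturity_stage %in% c(NA, 1:7)))
  # noiseless weights equal the rounded power law
  cfg0 <- generator_config(lw_sdlog = 0)
  one <- make_stations(7.25, 10)
  ind <- generate_individuals(one, cfg0, seed = 5)
  staged <- !is.na(ind$weight)
  expect_equal(ind$weight[staged],
               round(exp(-5.73 + 3.06 * log(ind$total_length[staged]))))
  # the generating ogive puts the maturity midpoint at 50 cm
  expect_equal(stats::plogis(cfg$ogive_beta0 + cfg$ogive_beta1 * 50), 0.5)
})

test_that("stomach generation respects emptiness and category structure", {
  cfg_all_empty <- generator_config(p_empty = 1)
  sto <- generate_stomachs(40, cfg_all_empty, seed = 3)
  expect_true(all(sto$is_empty))
  expect_true(all(rowSums(sto[, c("teleost", "crustacean", "cephalopod",
                                  "echinoderm", "unidentified")]) == 0))
  # single-category surveys: every stomach contains exactly that category
  cfg_tel <- generator_config(
    p_empty = 0,
    prey_presence = c(teleost = 1, crustacean = 0, cephalopod = 0,
                      echinoderm = 0, unidentified = 0))
  sto2 <- generate_stomachs(40, cfg_tel, seed = 3)
  expect_true(all(!sto2$is_empty))
  expect_true(all(sto2$teleost > 0))
  expect_true(all(sto2$crustacean == 0 & sto2$cephalopod == 0 &
                    sto2$echinoderm == 0 & sto2$unidentified == 0))
  # empirical empty fraction near p_empty (binomial bound at n = 2700)
  sto3 <- generate_stomachs(2700, generator_config(), seed = 8)
  expect_lt(abs(mean(sto3$is_empty) - 0.185),
            4 * sqrt(0.185 * 0.815 / 2700))
})

test_that("configuration invariants are enforced", {
  expect_error(generator_config(temp_sd = 0), class = "tn_config_error")
  expect_error(generator_config(catch_amplitude = -1),
               class = "tn_config_error")
  expect_error(generator_config(p_empty = 1.4), class = "tn_config_error")
  expect_error(generator_config(max_staged = -2), class = "tn_config_error")
})
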