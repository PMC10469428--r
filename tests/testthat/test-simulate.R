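test_that("identical config and seed reproduce identical output", {
  cfg <- sim_config(n_animals = 2, seed = 42)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a, b)
  da <- simulate_dives(a$truth, cfg)
  db <- simulate_dives(b$truth, cfg)
  expect_identical(da, db)
})

test_that("noise-free hourly observations reproduce the true positions", {
  cfg <- sim_config(n_animals = 1,
                    hours_per_phase = c(summer_res = 120, fall_move = 10,
                                        winter_res = 10, spring_move = 10),
                    gps_interval_min = c(60, 60), gps_error_m = 0,
                    gps_bad_rate = 0,
                    argos_interval_min = c(summer = Inf, winter = Inf),
                    outlier_rate = 0, gap_schedule = numeric(0), seed = 7)
  sim <- simulate_tracks(cfg)
  obs <- sim$locations
  tr <- sim$truth
  m <- match(paste(obs$id, as.numeric(obs$timestamp)),
             paste(tr$id, as.numeric(tr$timestamp)))
  on_hour <- !is.na(m)
  expect_gt(sum(on_hour), 50)
  expect_equal(obs$lon[on_hour], tr$lon[m[on_hour]], tolerance = 1e-9)
  expect_equal(obs$lat[on_hour], tr$lat[m[on_hour]], tolerance = 1e-9)
})

test_that("step and angle emissions match the configured state parameters", {
  p <- hmm_params(step_mean = c(2.09, 4.39), step_sd = c(1.37, 1.15),
                  kappa = c(1.22, 10.97))
  ser <- simulate_hmm_series(p, 30000, seed = 1)
  for (s in c("ARS", "Transit")) {
    i <- ser$state == s
    k <- if (s == "ARS") 1 else 2
    expect_equal(mean(ser$step_km[i]), p$step_mean[k], tolerance = 0.05)
    expect_equal(sd(ser$step_km[i]), p$step_sd[k], tolerance = 0.08)
    # kappa via the mean resultant length: E[cos(theta)] = I1(k)/I0(k)
    rbar <- mean(cos(ser$turn_rad[i]), na.rm = TRUE)
    rbar_expected <- besselI(p$kappa[k], 1) / besselI(p$kappa[k], 0)
    expect_equal(rbar, rbar_expected, tolerance = 0.05)
  }
  expect_true(all(ser$step_km > 0))
  expect_true(all(ser$turn_rad > -pi & ser$turn_rad <= pi, na.rm = TRUE))
})

test_that("winter GPS fixes fall only on every 7th day after the switch", {
  cfg <- sim_config(n_animals = 1, seed = 9,
                    argos_interval_min = c(summer = Inf, winter = Inf))
  sim <- simulate_tracks(cfg)
  tr <- sim$truth
  t_switch <- min(tr$timestamp[tr$programme == "winter"])
  w <- sim$locations[sim$locations$timestamp >= t_switch &
                       sim$locations$source == "GPS", ]
  expect_gt(nrow(w), 10)
  day <- floor(as.numeric(difftime(w$timestamp, t_switch, units = "days")))
  expect_true(all(day %% 7 == 0))
})

test_that("state dwell times follow the geometric law of the transition matrix", {
  G <- matrix(c(0.85, 0.05, 0.15, 0.95), 2, 2)
  p <- hmm_params(step_mean = c(2, 4), step_sd = c(1, 1), kappa = c(1, 10),
                  Gamma = G)
  ser <- simulate_hmm_series(p, rep(2000, 10), seed = 3)
  for (k in 1:2) {
    r <- rle(ser$state)
    dw <- r$lengths[r$values == c("ARS", "Transit")[k]]
    dw <- dw[-c(1, length(dw))]          # censored first/last runs
    stay <- G[k, k]
    tab <- table(factor(pmin(dw, 20), levels = 1:20))
    pr <- stay^(0:19) * (1 - stay)
    pr[20] <- stay^19                    # pooled tail
    chi <- suppressWarnings(chisq.test(as.vector(tab), p = pr))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("dive counts are Poisson with the state rate and types are the four foraging labels", {
  cfg <- sim_config(n_animals = 1, seed = 2)
  sim <- simulate_tracks(cfg)
  dv <- simulate_dives(sim$truth, cfg)
  expect_true(all(dv$dives$dive_type %in% foraging_dive_types()))
  # empirical mean per state against the configured total rate
  key <- paste(dv$hourly_counts$id, as.numeric(dv$hourly_counts$hour_start))
  tkey <- paste(sim$truth$id, as.numeric(sim$truth$timestamp))
  st <- sim$truth$state[match(key, tkey)]
  for (k in 1:2) {
    i <- st == c("ARS", "Transit")[k]
    lam <- sum(cfg$dive_rate_per_hour[k, ])
    n <- sum(i)
    expect_gt(n, 500)
    expect_lt(abs(mean(dv$hourly_counts$n_foraging[i]) - lam),
              4 * sqrt(lam / n))
    # counts follow Poisson dispersion
    expect_equal(var(dv$hourly_counts$n_foraging[i]) /
                   mean(dv$hourly_counts$n_foraging[i]), 1, tolerance = 0.15)
  }
})

test_that("zero dive rates give zero events and negative rates are rejected", {
  cfg <- sim_config(n_animals = 1,
                    hours_per_phase = c(summer_res = 100, fall_move = 10,
                                        winter_res = 10, spring_move = 10),
                    dive_rate_per_hour = matrix(0, 2, 4), seed = 5)
  sim <- simulate_tracks(cfg)
  dv <- simulate_dives(sim$truth, cfg)
  expect_identical(nrow(dv$dives), 0L)
  expect_error(sim_config(dive_rate_per_hour = matrix(-1, 2, 4)), "rates")
})

test_that("degenerate configurations are rejected with an explanation", {
  expect_error(sim_config(step_sd_km = c(0, 0)), "non-stochastic")
  expect_error(sim_config(transition_matrix = matrix(c(0.5, 0.5, 0.2, 0.2), 2, 2)),
               "row-stochastic")
  expect_error(sim_config(angle_concentration = c(-1, 5)), "concentration")
  expect_error(sim_config(missing_hour_rate = 1.2), "missing_hour_rate")
})

test_that("interchange CSVs round-trip through disk", {
  cfg <- sim_config(n_animals = 1,
                    hours_per_phase = c(summer_res = 100, fall_move = 20,
                                        winter_res = 20, spring_move = 20),
                    seed = 8)
  sim <- simulate_tracks(cfg)
  dv <- simulate_dives(sim$truth, cfg)
  td <- withr::local_tempdir()
  write_table_csv(sim$locations, file.path(td, "loc.csv"))
  write_table_csv(dv$dives, file.path(td, "dives.csv"))
  loc2 <- read_locations_csv(file.path(td, "loc.csv"))
  expect_equal(as.numeric(loc2$timestamp), as.numeric(sim$locations$timestamp))
  expect_equal(loc2$lon, sim$locations$lon, tolerance = 1e-9)
  d2 <- read_dives_csv(file.path(td, "dives.csv"))
  expect_equal(as.numeric(d2$start), round(as.numeric(dv$dives$start)))
})
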