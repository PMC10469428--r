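hourly_df <- function(x, y, seg = "A_s01", id = "A") {
  data.frame(id = id, segment = seg,
             timestamp = as.POSIXct("2018-08-01", tz = "UTC") + 3600 * seq_along(x),
             x_km = x, y_km = y)
}

test_that("steps and angles follow the planar geometry", {
  h <- hourly_df(x = c(0, 1, 2, 3, 4), y = rep(0, 5))
  s <- steps_and_angles(h)
  expect_equal(s$step_km, rep(1, 4))
  expect_equal(s$turn_rad, c(NA, 0, 0, 0))
  # exact reversal maps to pi
  h2 <- hourly_df(x = c(0, 1, 0), y = c(0, 0, 0))
  s2 <- steps_and_angles(h2)
  expect_equal(s2$turn_rad[2], pi)
  # never across segments
  h3 <- rbind(hourly_df(c(0, 1), c(0, 0), seg = "A_s01"),
              hourly_df(c(50, 51), c(0, 0), seg = "A_s02"))
  s3 <- steps_and_angles(h3)
  expect_equal(nrow(s3), 2)
  expect_true(all(s3$step_km == 1))
})

test_that("projected step lengths agree with geodesic distances at high latitude", {
  # a 5 km step at 75N, measured through the projection round-trip
  ctr <- c(lon = -140, lat = 75)
  p1 <- aeqd_unproject(10, 20, ctr["lon"], ctr["lat"])
  p2 <- aeqd_unproject(13, 24, ctr["lon"], ctr["lat"])     # 5 km away in plane
  d_geo <- geosphere::distGeo(c(p1$lon, p1$lat), c(p2$lon, p2$lat)) / 1000
  expect_equal(d_geo, 5, tolerance = 1e-3)
})

test_that("forward likelihood matches the mixture case and path enumeration", {
  p <- hmm_params(step_mean = c(1, 4), step_sd = c(1, 1.5), kappa = c(0.8, 9),
                  Gamma = matrix(c(0.8, 0.3, 0.2, 0.7), 2, 2))
  one <- data.frame(id = "A", segment = "A_s01",
                    timestamp = as.POSIXct("2018-08-01", tz = "UTC"),
                    step_km = 2.5, turn_rad = NA_real_)
  delta <- c(p$Gamma[2, 1], p$Gamma[1, 2]) / (p$Gamma[1, 2] + p$Gamma[2, 1])
  f <- vapply(1:2, function(s)
    dgamma(2.5, shape = (p$step_mean[s] / p$step_sd[s])^2,
           rate = p$step_mean[s] / p$step_sd[s]^2), numeric(1))
  expect_equal(forward_loglik(p, one), log(sum(delta * f)))
  # 3-step toy series equals the sum over all 8 paths
  toy <- simulate_hmm_series(p, 3, seed = 2)
  expect_equal(forward_loglik(p, toy), oracle_forward_ll(p, toy),
               tolerance = 1e-10)
  # relabelling symmetry
  p_swap <- hmm_params(rev(p$step_mean), rev(p$step_sd), rev(p$kappa),
                       p$Gamma[2:1, 2:1])
  expect_equal(forward_loglik(p_swap, toy), forward_loglik(p, toy),
               tolerance = 1e-12)
  # zero-step guard
  bad <- toy; bad$step_km[2] <- 0
  expect_error(forward_loglik(p, bad), "floor")
})

test_that("forward recursion equals path enumeration on many short multi-segment series", {
  set.seed(77)
  for (rep in 1:30) {
    rs <- random_series(c(sample(2:6, 1), sample(2:6, 1)), seed = 1000 + rep)
    expect_equal(forward_loglik(rs$params, rs$series),
                 oracle_forward_ll(rs$params, rs$series), tolerance = 1e-10)
  }
})

test_that("fitting from the m1 start recovers generating parameters and improves the likelihood", {
  p <- hmm_params(step_mean = c(2.09, 4.39), step_sd = c(1.37, 1.15),
                  kappa = c(1.22, 10.97),
                  Gamma = matrix(c(0.85, 0.05, 0.15, 0.95), 2, 2))
  ser <- simulate_hmm_series(p, rep(1000, 5), seed = 31)
  fit <- fit_hmm(ser)
  expect_gte(fit$loglik, fit$loglik_init)
  est <- fit$params
  expect_equal(est$step_mean, p$step_mean, tolerance = 0.05)
  expect_equal(est$step_sd, p$step_sd, tolerance = 0.08)
  expect_equal(est$kappa, p$kappa, tolerance = 0.15)
  expect_equal(est$Gamma[1, 2], 0.15, tolerance = 0.25)
  # labels are always ordered by step mean
  expect_lt(est$step_mean[1], est$step_mean[2])
})

test_that("degenerate fits are recognised", {
  p_bad <- hmm_params(step_mean = c(0.006, 4), step_sd = c(1, 1),
                      kappa = c(1, 10),
                      Gamma = matrix(c(1, 0, 0, 1), 2, 2))  # Transit->ARS = 0
  expect_true(movestates:::.is_degenerate(p_bad))
  p_ok <- hmm_params(step_mean = c(2, 4), step_sd = c(1, 1), kappa = c(1, 10))
  expect_false(movestates:::.is_degenerate(p_ok))
})

test_that("posterior decoding normalises, thresholds, and recovers well-separated states", {
  p <- hmm_params(step_mean = c(1, 6), step_sd = c(0.5, 1), kappa = c(0.5, 12),
                  Gamma = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  ser <- simulate_hmm_series(p, rep(500, 4), seed = 12)
  dec <- decode(p, ser)
  expect_equal(dec$P_ARS + dec$P_Transit, rep(1, nrow(dec)), tolerance = 1e-12)
  pm <- pmax(dec$P_ARS, dec$P_Transit)
  expect_true(all(dec$label[pm < 0.9] == "Uncertain"))
  expect_true(all(dec$label[pm >= 0.9] != "Uncertain"))
  hard <- dec$label != "Uncertain"
  expect_gte(mean(dec$label[hard] == ser$state[hard]), 0.95)
})

test_that("the multi-start protocol never silently accepts a divergent extreme start", {
  p <- hmm_params(step_mean = c(2.09, 4.39), step_sd = c(1.37, 1.15),
                  kappa = c(1.22, 10.97),
                  Gamma = matrix(c(0.85, 0.05, 0.15, 0.95), 2, 2))
  ser <- simulate_hmm_series(p, rep(800, 4), seed = 55)
  f1 <- fit_hmm(ser)
  inits <- c(list(m1 = hmm_m1_init()), hmm_init_protocol(f1, ser))
  fit <- suppressWarnings(fit_hmm(ser, init_sets = inits))
  dg <- fit$diagnostics
  expect_setequal(dg$init, c("m1", "m2", "m3", "m4", "m5"))
  m5 <- dg[dg$init == "m5", ]
  # m5 either agrees with the selected fit or is flagged -- never both clean
  # and different
  agreed <- isTRUE(!m5$non_identical) && isTRUE(m5$converged) && isTRUE(!m5$degenerate)
  flagged <- isTRUE(m5$degenerate) || isTRUE(m5$non_identical) || !isTRUE(m5$converged)
  expect_true(agreed || flagged)
  if (agreed)
    expect_equal(m5$mu_ARS, dg$mu_ARS[dg$init == fit$selected_init],
                 tolerance = 1e-3)
  # m1-m4 all converge to the same estimates on clean data
  core <- dg[dg$init %in% c("m1", "m2", "m3", "m4"), ]
  expect_true(all(core$converged))
  expect_lt(diff(range(core$mu_Transit)), 1e-2)
})

test_that("simulate() round-trips through the fitted model", {
  p <- hmm_params(step_mean = c(2, 5), step_sd = c(1, 1), kappa = c(1, 8),
                  Gamma = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  ser <- simulate_hmm_series(p, rep(600, 3), seed = 8)
  fit <- fit_hmm(ser)
  sim2 <- simulate(fit, seed = 9, segment_lengths = c(50, 50))
  expect_s3_class(sim2, "step_series")
  expect_equal(nrow(sim2), 100)
  expect_true(all(is.na(sim2$turn_rad[!duplicated(sim2$segment)])))
})
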