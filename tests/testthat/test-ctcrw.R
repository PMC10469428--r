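test_that("error ellipses map to planar covariances correctly", {
  expect_equal(ellipse_to_cov(50, 50, 0), diag(2) * 0.0025)
  # orientation 90 deg swaps the diagonal relative to 0 deg
  c0 <- ellipse_to_cov(500, 100, 0)
  c90 <- ellipse_to_cov(500, 100, 90)
  expect_equal(diag(c0), rev(diag(c90)))
  # general case against a direct rotation-matrix construction
  th <- 37 * pi / 180
  R <- matrix(c(sin(th), cos(th), cos(th), -sin(th)), 2, 2)  # cols: major, minor
  oracle <- R %*% diag(c(0.5^2, 0.1^2)) %*% t(R)
  expect_equal(ellipse_to_cov(500, 100, 37), oracle, tolerance = 1e-12)
  expect_warning(sw <- ellipse_to_cov(100, 500, 0), "swap")
  expect_equal(sw, ellipse_to_cov(500, 100, 0))
})

test_that("Kalman likelihood equals the dense joint-Gaussian evaluation", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    t_h <- cumsum(c(0, runif(n - 1, 0.2, 3)))
    obs <- cbind(cumsum(rnorm(n, 0, 2)), cumsum(rnorm(n, 0, 2)))
    smaj <- runif(n, 50, 1500); smin <- smaj * runif(n, 0.3, 1)
    or <- runif(n, 0, 180)
    cv <- t(mapply(function(a, b, o) {
      C <- ellipse_to_cov(a, b, o); c(C[1, 1], C[2, 2], C[1, 2])
    }, smaj, smin, or))
    beta <- runif(1, 0.2, 3); sigma <- runif(1, 0.5, 5)
    expect_equal(pkg_ctcrw_ll(t_h, obs, cv, beta, sigma),
                 oracle_ctcrw_ll(t_h, obs, cv, beta, sigma),
                 tolerance = 1e-6)
  }
})

test_that("fitting recovers known (beta, sigma) and improves on the start", {
  seg <- sim_iou_track(500, beta = 0.8, sigma = 3, seed = 11)
  fit <- fit_ctcrw(seg)
  expect_equal(unname(coef(fit)["beta"]), 0.8, tolerance = 0.25)
  expect_equal(unname(coef(fit)["sigma"]), 3, tolerance = 0.15)
  expect_gte(fit$loglik, fit$loglik_init)
  expect_false(fit$boundary)
})

test_that("a stationary animal drives the diffusion to its boundary and predicts the common position", {
  set.seed(5)
  n <- 60
  seg <- data.frame(timestamp = as.POSIXct("2018-08-01", tz = "UTC") +
                      cumsum(c(0, runif(n - 1, 0.4, 1.2))) * 3600,
                    x = 10 + rnorm(n, 0, 1e-4), y = -5 + rnorm(n, 0, 1e-4),
                    var_x = 1e-8, var_y = 1e-8, cov_xy = 0)
  fit <- fit_ctcrw(seg)
  expect_true(fit$boundary)
  pr <- predict(fit)
  expect_true(all(abs(pr$x - 10) < 0.01))
  expect_true(all(abs(pr$y + 5) < 0.01))
})

test_that("hourly prediction grid covers exactly the interior whole hours", {
  t0 <- as.POSIXct("2018-08-01 03:10:00", tz = "UTC")
  t1 <- as.POSIXct("2018-08-01 09:50:00", tz = "UTC")
  tt <- seq(t0, t1, length.out = 12)
  set.seed(3)
  seg <- data.frame(timestamp = tt, x = cumsum(rnorm(12)), y = cumsum(rnorm(12)),
                    var_x = 0.01, var_y = 0.01, cov_xy = 0)
  fit <- fit_ctcrw(seg)
  pr <- predict(fit)
  expect_equal(format(pr$timestamp, "%H:%M"),
               sprintf("%02d:00", 4:9))
})

test_that("smoothing reproduces near-exact observations and widens between them", {
  set.seed(9)
  tt <- as.POSIXct("2018-08-01", tz = "UTC") + c(0, 1, 2, 3, 9, 10, 11, 12) * 3600
  seg <- data.frame(timestamp = tt, x = c(0, 1, 2, 3, 8, 9, 10, 11) + rnorm(8, 0, 1e-3),
                    y = 0 + rnorm(8, 0, 1e-3),
                    var_x = 1e-6, var_y = 1e-6, cov_xy = 0)
  fit <- fit_ctcrw(seg)
  pr <- predict(fit)
  at_obs <- pr[pr$t_h %in% (as.numeric(tt) / 3600), ]
  m <- match(at_obs$t_h, as.numeric(tt) / 3600)
  expect_true(all(abs(at_obs$x - seg$x[m]) < 0.01))
  # prediction variance midway through the 6 h data gap exceeds the variance
  # at an observation time
  mid <- pr[which.min(abs(pr$t_h - (as.numeric(tt[4]) / 3600 + 3))), ]
  expect_gt(mid$var_x, max(at_obs$var_x) * 5)
})

test_that("refining the prediction grid leaves shared-grid predictions unchanged", {
  seg <- sim_iou_track(40, beta = 1, sigma = 2, seed = 21)
  fit <- fit_ctcrw(seg)
  pr <- predict(fit)
  # rerun the smoother with extra half-hour marks inserted
  t_h <- as.numeric(seg$timestamp) / 3600
  extra <- sort(unique(c(t_h, pr$t_h, pr$t_h[-1] - 0.5)))
  has <- as.integer(vapply(extra, function(t) any(abs(t - t_h) < 1e-9), logical(1)))
  obs <- matrix(0, length(extra), 2); R <- matrix(0, length(extra), 3)
  i <- match(round(t_h, 9), round(extra, 9))
  obs[i, ] <- cbind(seg$x, seg$y); R[i, ] <- cbind(seg$var_x, seg$var_y, seg$cov_xy)
  sm <- movestates:::.ctcrw_kalman(extra, has, obs, R, fit$beta, fit$sigma,
                                   fit$p0_pos, fit$p0_vel, TRUE)
  j <- match(pr$t_h, round(extra, 9))
  expect_equal(sm$x[j], pr$x, tolerance = 1e-8)
  expect_equal(sm$var_x[j], pr$var_x, tolerance = 1e-8)
})

test_that("hourly interpolation flags unrealistic modelled speeds", {
  cfg <- sim_config(n_animals = 1,
                    hours_per_phase = c(summer_res = 250, fall_move = 50,
                                        winter_res = 40, spring_move = 40),
                    seed = 17)
  sim <- simulate_tracks(cfg)
  qc <- qc_track(sim$locations)
  ip <- interpolate_hourly(qc$segments)
  expect_true(all(c("speed_flag", "lon", "lat", "var_x") %in% names(ip$hourly)))
  # hourly positions track the truth closely where both exist
  tr <- sim$truth
  m <- match(paste(ip$hourly$id, as.numeric(ip$hourly$timestamp)),
             paste(tr$id, as.numeric(tr$timestamp)))
  ok <- !is.na(m)
  expect_gt(mean(ok), 0.8)
  dx <- ip$hourly$x_km[ok]; dy <- ip$hourly$y_km[ok]
  # compare in each animal's projection via geographic distance instead
  d_km <- geosphere::distGeo(cbind(ip$hourly$lon[ok], ip$hourly$lat[ok]),
                             cbind(tr$lon[m[ok]], tr$lat[m[ok]])) / 1000
  expect_lt(median(d_km), 1)
})
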