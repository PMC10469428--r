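ts0 <- as.POSIXct("2018-08-01 00:00:00", tz = "UTC")

test_that("GPS quality filter applies the satellite/residual rules and assigns the nominal ellipse", {
  x <- rbind(
    loc_row(timestamp = ts0,          source = "GPS", n_sat = 4, residual = 10,
            smaj_m = NA, smin_m = NA, orient_deg = NA),
    loc_row(timestamp = ts0 + 60,     source = "GPS", n_sat = 6, residual = 36,
            smaj_m = NA, smin_m = NA, orient_deg = NA),
    loc_row(timestamp = ts0 + 120,    source = "GPS", n_sat = 5, residual = 35,
            smaj_m = NA, smin_m = NA, orient_deg = NA),
    loc_row(timestamp = ts0 + 180,    source = "Argos", smaj_m = 5000))
  out <- qc_gps(x)
  expect_equal(sum(out$source == "GPS"), 1)       # only (5, 35) survives
  g <- out[out$source == "GPS", ]
  expect_equal(as.numeric(g$timestamp), as.numeric(ts0 + 120))
  expect_equal(c(g$smaj_m, g$smin_m, g$orient_deg), c(50, 50, 0))
  expect_equal(out$smaj_m[out$source == "Argos"], 5000)  # Argos untouched here
  # missing quality fields on a GPS row: removed with a warning
  y <- loc_row(timestamp = ts0, source = "GPS", n_sat = NA, residual = 5,
               smaj_m = NA, smin_m = NA, orient_deg = NA)
  expect_warning(out2 <- qc_gps(y), "missing quality")
  expect_equal(nrow(out2), 0)
})

test_that("Argos ellipse filter removes strictly above 3 km and keeps the boundary", {
  x <- rbind(loc_row(timestamp = ts0, smaj_m = 3001),
             loc_row(timestamp = ts0 + 60, smaj_m = 3000),
             loc_row(timestamp = ts0 + 120, smaj_m = 500))
  out <- qc_argos_error(x)
  expect_equal(out$smaj_m, c(3000, 500))
  expect_equal(nrow(qc_argos_error(x[0, ])), 0)
})

test_that("speed filter keeps slow collinear tracks and removes fast spikes", {
  # three collinear points at ~1 m/s (3.6 km/h along a meridian)
  lat <- c(70, 70 + 3.6 / 111.3, 70 + 7.2 / 111.3)
  x <- do.call(rbind, lapply(1:3, function(i)
    loc_row(timestamp = ts0 + (i - 1) * 3600, lat = lat[i])))
  expect_equal(nrow(sda_filter(x)), 3)
  # middle point requiring ~6 m/s both ways
  lat2 <- c(70, 70 + 21.6 / 111.3, 70)
  y <- do.call(rbind, lapply(1:3, function(i)
    loc_row(timestamp = ts0 + (i - 1) * 3600, lat = lat2[i])))
  out <- sda_filter(y)
  expect_equal(nrow(out), 2)
  expect_false(any(abs(out$lat - lat2[2]) < 1e-9))
  # fewer than 3 locations returned unchanged
  expect_equal(nrow(sda_filter(y[1:2, ])), 2)
})

test_that("spike filter honours both the angle and the excursion thresholds", {
  mk_spike <- function(exc_m) {
    # out-and-back with inner angle ~10 degrees at the tip, slow enough to
    # pass the speed stage
    d_deg <- exc_m / 1000 / 111.3
    off <- d_deg * tan(5 * pi / 180)     # half-angle 5 deg => inner angle 10
    rbind(loc_row(timestamp = ts0, lat = 70, lon = 0),
          loc_row(timestamp = ts0 + 12 * 3600, lat = 70 + d_deg, lon = off / cos(70 * pi / 180)),
          loc_row(timestamp = ts0 + 24 * 3600, lat = 70, lon = 2 * off / cos(70 * pi / 180)))
  }
  big <- sda_filter(mk_spike(3000))
  expect_equal(nrow(big), 2)                 # 3,000 m excursion: removed
  small <- sda_filter(mk_spike(2000))
  expect_equal(nrow(small), 3)               # same shape at 2,000 m: retained
})

test_that("Argos fixes strictly within 10 min of a GPS fix are removed", {
  x <- rbind(loc_row(timestamp = ts0, source = "GPS", n_sat = 7, residual = 1,
                     smaj_m = 50, smin_m = 50, orient_deg = 0),
             loc_row(timestamp = ts0 + 9 * 60),
             loc_row(timestamp = ts0 + 10 * 60),
             loc_row(timestamp = ts0 + 11 * 60))
  out <- dedup_argos_near_gps(x)
  expect_equal(sum(out$source == "GPS"), 1)
  kept <- as.numeric(out$timestamp[out$source == "Argos"] - ts0, units = "secs")
  expect_equal(kept, c(600, 660))            # 9 min removed; 10 and 11 kept
})

test_that("low-accuracy fixes are pruned only near a good fix", {
  mk <- function(gap_min) rbind(
    loc_row(timestamp = ts0, smaj_m = 400),
    loc_row(timestamp = ts0 + gap_min * 60, smaj_m = 600))
  expect_equal(nrow(prune_low_accuracy(mk(15))), 1)   # removed
  expect_equal(nrow(prune_low_accuracy(mk(25))), 2)   # kept
  # 500 m is never removed by this rule
  x <- rbind(loc_row(timestamp = ts0, smaj_m = 100),
             loc_row(timestamp = ts0 + 60, smaj_m = 500))
  expect_equal(nrow(prune_low_accuracy(x)), 2)
})

test_that("segmentation splits at >6 h gaps and drops short fragments", {
  tt <- c(0, 1, 2, 3, 9.0167, 10, 11, 12.1) * 3600   # gap of 6 h 1 min
  x <- do.call(rbind, lapply(tt, function(s) loc_row(timestamp = ts0 + s)))
  out <- segment_track(x)
  expect_equal(length(unique(out$segment)), 2)
  # a 3-location fragment is dropped
  y <- do.call(rbind, lapply(c(0, 1, 2, 3, 11, 12, 13) * 3600,
                             function(s) loc_row(timestamp = ts0 + s)))
  out2 <- segment_track(y)
  expect_equal(length(unique(out2$segment)), 1)
  expect_equal(nrow(out2), 4)
  # 5 locations spanning 2.9 h are dropped
  z <- do.call(rbind, lapply(seq(0, 2.9, length.out = 5) * 3600,
                             function(s) loc_row(timestamp = ts0 + s)))
  expect_equal(nrow(segment_track(z)), 0)
  expect_equal(nrow(segment_track(z[0, ])), 0)
})

test_that("the full cascade is idempotent and never edits surviving coordinates", {
  cfg <- sim_config(n_animals = 2, seed = 21)
  sim <- simulate_tracks(cfg)
  qc1 <- qc_track(sim$locations)
  # removal-only: every surviving (timestamp, lon, lat) existed in the input
  k_in <- paste(sim$locations$id, as.numeric(sim$locations$timestamp),
                round(sim$locations$lon, 9), round(sim$locations$lat, 9))
  k_out <- paste(qc1$segments$id, as.numeric(qc1$segments$timestamp),
                 round(qc1$segments$lon, 9), round(qc1$segments$lat, 9))
  expect_true(all(k_out %in% k_in))
  expect_false(is.unsorted(qc1$segments$timestamp[qc1$segments$id == "SIM01"]))
  # idempotence on its own output
  qc2 <- qc_track(qc1$segments[names(sim$locations)])
  expect_equal(nrow(qc2$segments), nrow(qc1$segments))
  expect_equal(qc2$segments$lon, qc1$segments$lon)
  # the per-stage count chain never increases
  expect_true(all(diff(qc1$report$n) <= 0))
})

test_that("noise-free fixes all survive and injected outliers are removed", {
  cfg <- sim_config(n_animals = 1,
                    hours_per_phase = c(summer_res = 200, fall_move = 50,
                                        winter_res = 50, spring_move = 50),
                    gps_error_m = 0, gps_bad_rate = 0,
                    argos_interval_min = c(summer = Inf, winter = Inf),
                    outlier_rate = 0, gap_schedule = numeric(0), seed = 13)
  sim <- simulate_tracks(cfg)
  qc <- qc_track(sim$locations)
  expect_equal(nrow(qc$segments), nrow(sim$locations))
  # now with outliers: every surviving consecutive pair respects 5 m/s by a
  # wide margin (the generator shifts outliers 5-50 km off track)
  cfg2 <- sim_config(n_animals = 1, seed = 13)
  sim2 <- simulate_tracks(cfg2)
  qc2 <- qc_track(sim2$locations)
  for (seg in split(qc2$segments, qc2$segments$segment)) {
    if (nrow(seg) < 3) next
    d <- geosphere::distGeo(cbind(seg$lon[-nrow(seg)], seg$lat[-nrow(seg)]),
                            cbind(seg$lon[-1], seg$lat[-1]))
    dt <- diff(as.numeric(seg$timestamp))
    v <- d / pmax(dt, 1)
    # interior points cannot require >5 m/s from both sides
    n <- length(v)
    if (n >= 2) expect_true(all(pmin(v[-n], v[-1]) <= 5 + 1e-6))
  }
})
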