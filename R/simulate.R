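#' Configuration for the synthetic track-and-dive generator
#'
#' Builds the parameter set for [simulate_tracks()] and [simulate_dives()].
#' The defaults describe a small population of Arctic belugas tagged in
#' mid-summer: a summer residency period, a meandering fall long-distance
#' movement to a winter area ~1400 km away, a duty-cycled winter residency
#' (GPS on every 7th day only), and a spring return movement.  Movement is a
#' two-state Markov-switching correlated random walk — slow, tortuous
#' area-restricted search (ARS) versus fast, directionally persistent Transit —
#' with gamma step lengths and von Mises turning angles, the exact emission
#' structure the hidden Markov model downstream assumes.  State parameters
#' default to the fitted values for this population (step means 2.09/4.39 km,
#' sds 1.37/1.15 km, concentrations 1.22/10.97).
#'
#' Two transition matrices are used because state occupancy differs sharply
#' between movement and residency: the movement-phase default has stationary
#' Transit occupancy 0.75, the residency default 0.40, matching the observed
#' 75.4% vs 39.1% Transit time.
#'
#' @param n_animals number of simulated animals.
#' @param hours_per_phase named numeric: maximum hours in `summer_res`,
#'   `fall_move`, `winter_res`, `spring_move`.  Movement phases end early when
#'   the animal arrives within `arrival_radius_km` of its destination, so
#'   realised durations vary between animals.
#' @param transition_matrix 2x2 row-stochastic state transition matrix
#'   (rows/cols ordered ARS, Transit) used during movement phases.
#' @param residency_transition_matrix same, used during residency phases.
#' @param step_mean_km,step_sd_km length-2 (ARS, Transit) gamma step-length
#'   mean and sd in km per hour.
#' @param angle_concentration length-2 von Mises turning-angle concentrations
#'   (mean angle fixed at 0 for both states).
#' @param gps_interval_min length-2 range (min, max) of minutes between GPS
#'   fixes while the tag is in its summer programme.
#' @param winter_gps_period_days GPS duty cycle after the winter switch: GPS
#'   is collected only on every `winter_gps_period_days`-th day.
#' @param argos_interval_min named numeric, mean minutes between Argos fixes
#'   in `summer` and `winter` tag programmes (exponential gaps); `Inf`
#'   disables Argos.
#' @param gps_error_m isotropic 1-sigma GPS measurement error (m).
#' @param gps_bad_rate fraction of GPS fixes with failing quality fields
#'   (< 5 satellites or residual > 35); these also get inflated error.
#' @param argos_error_ellipse_dist list with `smaj_meanlog`, `smaj_sdlog`
#'   (log-normal semi-major axis, m), `smin_frac` range (semi-minor as a
#'   fraction of semi-major) and `orient_range` (degrees).
#' @param outlier_rate fraction of Argos fixes displaced far off-track with a
#'   grossly inflated error ellipse, so the QC filters have real work to do.
#' @param outlier_shift_km range of outlier displacement distances.
#' @param gap_schedule gap lengths (h) each inserted once per animal at a
#'   random time before the winter switch (observations inside are dropped).
#' @param dive_rate_per_hour 2x4 matrix of Poisson foraging-dive rates per
#'   hour, rows ARS/Transit, columns the four foraging dive types.  The
#'   population's data do not pin these down; the defaults give ARS hours a
#'   higher total rate (2.5/h) than Transit hours (1.8/h) and are free
#'   parameters.
#' @param missing_hour_rate long-run fraction of hours with missing depth
#'   data; missingness arrives in runs (mean complete run
#'   `missing_run_mean_h` * (1-rate)/rate hours).
#' @param missing_run_mean_h mean length (h) of a missing-data run.
#' @param summer_centre,winter_centre named (lon, lat) centres of the two
#'   residency areas.
#' @param arrival_radius_km movement phases end when the animal is within this
#'   distance of the destination centre.
#' @param residency_radius_km during residency, headings are nudged back
#'   toward the phase centre once the animal is farther out than this.
#' @param nav_gain weight (0-1) of the per-hour heading correction toward the
#'   destination while in Transit during a movement phase; small values give
#'   realistic meandering rather than beeline tracks.
#' @param start_time POSIXct deployment time of the first animal; animals
#'   start at random whole hours within 5 days of it.
#' @param seed integer seed; identical configs (same seed) reproduce the same
#'   animals exactly.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_tracks()], [simulate_dives()]
#' @export
sim_config <- function(n_animals = 6,
                       hours_per_phase = c(summer_res = 600, fall_move = 1500,
                                           winter_res = 1400, spring_move = 800),
                       transition_matrix = matrix(c(0.85, 0.05, 0.15, 0.95), 2, 2),
                       residency_transition_matrix = matrix(c(0.90, 0.15, 0.10, 0.85), 2, 2),
                       step_mean_km = c(ARS = 2.09, Transit = 4.39),
                       step_sd_km = c(ARS = 1.37, Transit = 1.15),
                       angle_concentration = c(ARS = 1.22, Transit = 10.97),
                       gps_interval_min = c(7, 30),
                       winter_gps_period_days = 7,
                       argos_interval_min = c(summer = 60, winter = 180),
                       gps_error_m = 25,
                       gps_bad_rate = 0.05,
                       argos_error_ellipse_dist = list(smaj_meanlog = log(800),
                                                       smaj_sdlog = 0.8,
                                                       smin_frac = c(0.3, 1),
                                                       orient_range = c(0, 180)),
                       outlier_rate = 0.02,
                       outlier_shift_km = c(5, 50),
                       gap_schedule = c(8, 12, 24, 36),
                       dive_rate_per_hour = rbind(ARS = c(0.9, 0.6, 0.6, 0.4),
                                                  Transit = c(0.6, 0.45, 0.45, 0.3)),
                       missing_hour_rate = 0.6,
                       missing_run_mean_h = 6,
                       summer_centre = c(lon = -134, lat = 70.5),
                       winter_centre = c(lon = -170, lat = 68.5),
                       arrival_radius_km = 100,
                       residency_radius_km = 150,
                       nav_gain = 0.08,
                       start_time = as.POSIXct("2018-07-10 00:00:00", tz = "UTC"),
                       seed = 1L) {
  cfg <- list(n_animals = as.integer(n_animals),
              hours_per_phase = hours_per_phase,
              transition_matrix = transition_matrix,
              residency_transition_matrix = residency_transition_matrix,
              step_mean_km = unname(step_mean_km), step_sd_km = unname(step_sd_km),
              angle_concentration = unname(angle_concentration),
              gps_interval_min = gps_interval_min,
              winter_gps_period_days = winter_gps_period_days,
              argos_interval_min = argos_interval_min,
              gps_error_m = gps_error_m, gps_bad_rate = gps_bad_rate,
              argos_error_ellipse_dist = argos_error_ellipse_dist,
              outlier_rate = outlier_rate, outlier_shift_km = outlier_shift_km,
              gap_schedule = gap_schedule,
              dive_rate_per_hour = dive_rate_per_hour,
              missing_hour_rate = missing_hour_rate,
              missing_run_mean_h = missing_run_mean_h,
              summer_centre = summer_centre, winter_centre = winter_centre,
              arrival_radius_km = arrival_radius_km,
              residency_radius_km = residency_radius_km,
              nav_gain = nav_gain,
              start_time = start_time, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  req <- c("summer_res", "fall_move", "winter_res", "spring_move")
  if (!all(req %in% names(cfg$hours_per_phase)))
    stop("hours_per_phase must name ", paste(req, collapse = ", "))
  for (nm in c("transition_matrix", "residency_transition_matrix")) {
    G <- cfg[[nm]]
    if (!is.matrix(G) || any(dim(G) != 2) || any(G < 0) ||
        any(abs(rowSums(G) - 1) > 1e-8))
      stop(nm, " must be a 2x2 row-stochastic matrix")
  }
  if (any(cfg$step_mean_km <= 0)) stop("step means must be positive")
  if (any(cfg$step_sd_km <= 0))
    stop("step sds must be strictly positive: a non-stochastic movement model ",
         "(zero step variance) generates degenerate tracks that the ",
         "downstream likelihoods cannot handle")
  if (any(cfg$angle_concentration < 0)) stop("angle concentrations must be >= 0")
  if (any(cfg$dive_rate_per_hour < 0)) stop("dive rates must be >= 0")
  if (cfg$missing_hour_rate < 0 || cfg$missing_hour_rate >= 1)
    stop("missing_hour_rate must be in [0, 1)")
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1) stop("outlier_rate in [0,1]")
  invisible(cfg)
}

# von Mises sampler (Best & Fisher 1979 rejection algorithm), mean 0
rvonmises0 <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  out
}

.states <- c("ARS", "Transit")
.phases <- c("summer_res", "fall_move", "winter_res", "spring_move")

# simulate one animal's true hourly path in the shared planar frame (km)
.sim_truth_one <- function(cfg, start_xy, targets) {
  hp <- cfg$hours_per_phase
  n_max <- sum(hp)
  state <- integer(n_max); phase <- integer(n_max); dyn <- integer(n_max)
  x <- numeric(n_max + 1); y <- numeric(n_max + 1)
  x[1] <- start_xy[1]; y[1] <- start_xy[2]
  # targets: list(summer = c(x,y), winter = c(x,y))
  Gres <- cfg$residency_transition_matrix
  Gmov <- cfg$transition_matrix
  pr_res <- Gres[2, 1] / (Gres[1, 2] + Gres[2, 1])     # stationary P(ARS)
  s <- if (runif(1) < pr_res) 1L else 2L
  heading <- runif(1, -pi, pi)
  ph <- 1L; ph_h <- 0L
  i <- 0L
  while (i < n_max && ph <= 4L) {
    i <- i + 1L; ph_h <- ph_h + 1L
    movement <- ph %in% c(2L, 4L)
    G <- if (movement) Gmov else Gres
    s <- if (runif(1) < G[s, 1]) 1L else 2L
    turn <- rvonmises0(1, cfg$angle_concentration[s])
    heading <- .wrap_angle(heading + turn)
    tgt <- switch(ph, targets$summer, targets$winter, targets$winter, targets$summer)
    d_tgt <- sqrt((tgt[1] - x[i])^2 + (tgt[2] - y[i])^2)
    pull <- if (movement && s == 2L) cfg$nav_gain
            else if (!movement && d_tgt > cfg$residency_radius_km) cfg$nav_gain
            else 0
    if (pull > 0) {
      bearing <- atan2(tgt[2] - y[i], tgt[1] - x[i])
      heading <- .wrap_angle(heading + pull * .wrap_angle(bearing - heading))
    }
    mu <- cfg$step_mean_km[s]; sdv <- cfg$step_sd_km[s]
    step <- rgamma(1, shape = (mu / sdv)^2, rate = mu / sdv^2)
    x[i + 1] <- x[i] + step * cos(heading)
    y[i + 1] <- y[i] + step * sin(heading)
    state[i] <- s
    # the long-distance phase is a spatial notion: movement-phase hours still
    # within the residency radius of the leg's origin or destination count as
    # residency, so the truth label flips where the track leaves/enters the
    # residency areas rather than on the schedule tick
    ph_rec <- ph
    if (movement) {
      orig <- switch(ph, NULL, targets$summer, NULL, targets$winter)
      d_orig <- sqrt((orig[1] - x[i])^2 + (orig[2] - y[i])^2)
      if (d_orig <= cfg$residency_radius_km || d_tgt <= cfg$residency_radius_km)
        ph_rec <- ph - 1L
    }
    phase[i] <- ph_rec
    dyn[i] <- ph
    arrived <- movement && d_tgt <= cfg$arrival_radius_km
    if (ph_h >= hp[ph] || arrived) { ph <- ph + 1L; ph_h <- 0L }
  }
  n <- i
  dyn <- dyn[seq_len(n)]
  # the tag programme switches to its winter setup when the winter residency
  # phase begins (mirrors reprogramming to a low duty cycle in late fall)
  winter_start_h <- if (any(dyn >= 3L)) min(which(dyn >= 3L)) - 1L else n
  list(n = n, x = x[seq_len(n + 1)], y = y[seq_len(n + 1)],
       state = state[seq_len(n)], phase = phase[seq_len(n)], dyn = dyn,
       winter_start_h = winter_start_h)
}

#' Simulate true tracks and corrupted observations
#'
#' Generates, for each animal, the true hourly path (two-state switching
#' correlated random walk between seasonal residency areas) and a raw
#' observation table mimicking a mixed Fastloc-GPS/Argos tag: duty-cycled
#' irregular sampling, source-specific measurement error drawn from error
#' ellipses, a fraction of quality-failing GPS fixes, gross Argos outliers,
#' and scheduled data gaps longer than 6 h.
#'
#' Observations are taken from the true path by linear interpolation in time,
#' then corrupted in the planar frame and back-projected to lon/lat.  With
#' zero measurement error, no outliers and exactly hourly fixes the observed
#' positions reproduce the true positions.
#'
#' @param config a [sim_config()] object.
#' @return list with elements
#'   \describe{
#'     \item{truth}{data frame, one row per simulated hour: `id`, `hour`
#'       (index from the animal's start), `timestamp`, `state`
#'       (`ARS`/`Transit`, the state governing the step out of this hour),
#'       `phase` (`residency`/`fall`/`spring`), `programme` (the tag's
#'       `summer`/`winter` duty-cycle setup), `x_km`, `y_km`, `lon`, `lat`.}
#'     \item{locations}{raw observation data frame with columns `id`,
#'       `timestamp`, `lon`, `lat`, `source`, `n_sat`, `residual`, `smaj_m`,
#'       `smin_m`, `orient_deg`.}
#'     \item{proj_centre}{named (lon, lat) of the shared planar frame.}
#'   }
#' @export
simulate_tracks <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  # shared planar frame centred between the two residency areas
  ctr <- .centroid_lonlat(c(cfg$summer_centre["lon"], cfg$winter_centre["lon"]),
                          c(cfg$summer_centre["lat"], cfg$winter_centre["lat"]))
  sc <- aeqd_project(cfg$summer_centre["lon"], cfg$summer_centre["lat"], ctr["lon"], ctr["lat"])
  wc <- aeqd_project(cfg$winter_centre["lon"], cfg$winter_centre["lat"], ctr["lon"], ctr["lat"])
  targets <- list(summer = c(sc$x, sc$y), winter = c(wc$x, wc$y))

  truth_list <- vector("list", cfg$n_animals)
  obs_list <- vector("list", cfg$n_animals)
  for (a in seq_len(cfg$n_animals)) {
    id <- sprintf("SIM%02d", a)
    t0 <- cfg$start_time + 3600 * sample.int(120, 1)
    start_xy <- c(targets$summer[1] + rnorm(1, 0, 30),
                  targets$summer[2] + rnorm(1, 0, 30))
    tr <- .sim_truth_one(cfg, start_xy, targets)
    ll <- aeqd_unproject(tr$x, tr$y, ctr["lon"], ctr["lat"])
    truth_list[[a]] <- data.frame(
      id = id, hour = seq_len(tr$n) - 1L,
      timestamp = t0 + 3600 * (seq_len(tr$n) - 1L),
      state = .states[tr$state],
      phase = c("residency", "fall", "residency", "spring")[tr$phase],
      programme = ifelse(seq_len(tr$n) - 1L < tr$winter_start_h, "summer", "winter"),
      x_km = tr$x[seq_len(tr$n)], y_km = tr$y[seq_len(tr$n)],
      lon = ll$lon[seq_len(tr$n)], lat = ll$lat[seq_len(tr$n)])
    obs_list[[a]] <- .sim_obs_one(cfg, tr, t0, id, ctr)
  }
  truth <- do.call(rbind, truth_list)
  locations <- do.call(rbind, obs_list)
  rownames(truth) <- rownames(locations) <- NULL
  list(truth = truth, locations = locations, proj_centre = ctr)
}

# observation process for one animal; tr as returned by .sim_truth_one
.sim_obs_one <- function(cfg, tr, t0, id, ctr) {
  n <- tr$n
  winter_start_h <- tr$winter_start_h
  # --- observation times (hours since t0, continuous) ---
  gps_t <- c(); t <- 0
  lo <- cfg$gps_interval_min[1] / 60; hi <- cfg$gps_interval_min[2] / 60
  while (t < winter_start_h) { gps_t <- c(gps_t, t); t <- t + runif(1, lo, hi) }
  # winter duty cycle: GPS only on every k-th day after the switch
  k <- cfg$winter_gps_period_days
  t <- winter_start_h
  while (t < n) {
    day <- floor((t - winter_start_h) / 24)
    if (day %% k == 0) { gps_t <- c(gps_t, t); t <- t + runif(1, lo, hi) }
    else t <- (winter_start_h + (day + 1) * 24)   # jump to next day
  }
  argos_t <- c()
  mi <- cfg$argos_interval_min
  if (is.finite(mi[["summer"]])) {
    t <- runif(1, 0, mi[["summer"]] / 60)
    while (t < winter_start_h) { argos_t <- c(argos_t, t); t <- t + rexp(1, 60 / mi[["summer"]]) }
  }
  if (is.finite(mi[["winter"]])) {
    t <- winter_start_h + rexp(1, 60 / mi[["winter"]])
    while (t < n) { argos_t <- c(argos_t, t); t <- t + rexp(1, 60 / mi[["winter"]]) }
  }
  # --- scheduled gaps (pre-winter) ---
  drop_win <- lapply(cfg$gap_schedule, function(g) {
    s <- runif(1, 0, max(winter_start_h - g, 1)); c(s, s + g)
  })
  keep <- function(tt) {
    ok <- rep(TRUE, length(tt))
    for (w in drop_win) ok <- ok & !(tt >= w[1] & tt <= w[2])
    ok
  }
  gps_t <- gps_t[keep(gps_t)]; argos_t <- argos_t[keep(argos_t)]

  interp <- function(tt) {
    i0 <- pmin(pmax(floor(tt), 0), n - 1)
    f <- tt - i0
    cbind(tr$x[i0 + 1] * (1 - f) + tr$x[i0 + 2] * f,
          tr$y[i0 + 1] * (1 - f) + tr$y[i0 + 2] * f)
  }
  rows <- list()
  if (length(gps_t)) {
    p <- interp(gps_t)
    ng <- length(gps_t)
    bad <- runif(ng) < cfg$gps_bad_rate
    err_sd <- ifelse(bad, 0.5, cfg$gps_error_m / 1000)   # km
    p <- p + cbind(rnorm(ng, 0, err_sd), rnorm(ng, 0, err_sd))
    n_sat <- ifelse(bad & runif(ng) < 0.5, sample(3:4, ng, TRUE), sample(5:11, ng, TRUE))
    residual <- ifelse(bad & n_sat >= 5, runif(ng, 36, 120), runif(ng, 0, 35))
    rows$gps <- data.frame(t = gps_t, x = p[, 1], y = p[, 2], source = "GPS",
                           n_sat = n_sat, residual = round(residual, 1),
                           smaj_m = NA_real_, smin_m = NA_real_, orient_deg = NA_real_)
  }
  if (length(argos_t)) {
    na_ <- length(argos_t)
    e <- cfg$argos_error_ellipse_dist
    smaj <- exp(rnorm(na_, e$smaj_meanlog, e$smaj_sdlog))
    smin <- smaj * runif(na_, e$smin_frac[1], e$smin_frac[2])
    orient <- runif(na_, e$orient_range[1], e$orient_range[2])
    out <- runif(na_) < cfg$outlier_rate
    smaj[out] <- smaj[out] * 8
    p <- interp(argos_t)
    # ellipse axes are 1-sigma; orientation measured from north (y axis)
    th <- (90 - orient) * pi / 180
    z1 <- rnorm(na_, 0, smaj / 1000); z2 <- rnorm(na_, 0, smin / 1000)
    p[, 1] <- p[, 1] + z1 * cos(th) - z2 * sin(th)
    p[, 2] <- p[, 2] + z1 * sin(th) + z2 * cos(th)
    if (any(out)) {
      sh <- runif(sum(out), cfg$outlier_shift_km[1], cfg$outlier_shift_km[2])
      an <- runif(sum(out), -pi, pi)
      p[out, 1] <- p[out, 1] + sh * cos(an)
      p[out, 2] <- p[out, 2] + sh * sin(an)
    }
    rows$argos <- data.frame(t = argos_t, x = p[, 1], y = p[, 2], source = "Argos",
                             n_sat = NA_integer_, residual = NA_real_,
                             smaj_m = round(smaj, 1), smin_m = round(smin, 1),
                             orient_deg = round(orient, 1))
  }
  if (!length(rows)) return(NULL)
  ob <- do.call(rbind, rows)
  ob <- ob[order(ob$t), , drop = FALSE]
  ll <- aeqd_unproject(ob$x, ob$y, ctr["lon"], ctr["lat"])
  data.frame(id = id, timestamp = t0 + floor(3600 * ob$t),
             lon = ll$lon, lat = ll$lat, source = ob$source,
             n_sat = ob$n_sat, residual = ob$residual,
             smaj_m = ob$smaj_m, smin_m = ob$smin_m, orient_deg = ob$orient_deg)
}

.foraging_types <- c("Deep Benthic", "Deep Pelagic V", "Deep Pelagic W",
                     "Intermediate Benthic")
# typical max-depth ranges (m) by foraging type, loosely after published
# beluga dive-shape classes
.type_depth_range <- list(`Deep Benthic` = c(200, 800),
                          `Deep Pelagic V` = c(150, 700),
                          `Deep Pelagic W` = c(150, 700),
                          `Intermediate Benthic` = c(50, 200))

#' Simulate dive events and an hourly depth-data completeness mask
#'
#' For every true hour, draws foraging-dive counts from independent Poisson
#' distributions per dive type with state-dependent rates, places dive start
#' times uniformly within the hour, and assigns dive durations and max depths.
#' Depth-record missingness arrives in runs (a two-state renewal process) with
#' long-run missing fraction `missing_hour_rate`, emulating patchy satellite
#' throughput.
#'
#' @param truth truth data frame from [simulate_tracks()] (contiguous hours
#'   per animal).
#' @param config the same [sim_config()] used for the tracks.
#' @return list with `dives` (data frame: `id`, `start`, `dive_type`,
#'   `max_depth_m`, `duration_s`), `mask` (data frame: `id`, `hour_start`,
#'   `has_depth_data`), and `hourly_counts` (the ground truth: `id`,
#'   `hour_start`, `n_foraging` per simulated hour).
#' @export
simulate_dives <- function(truth, config) {
  validate_sim_config(config)
  cfg <- config
  if (any(cfg$dive_rate_per_hour < 0)) stop("negative dive rates")
  set.seed(cfg$seed + 7919L)   # offset so dives are independent of the tracks
  rates <- cfg$dive_rate_per_hour
  dl <- list(); ml <- list(); hc <- list()
  for (id in unique(truth$id)) {
    tt <- truth[truth$id == id, ]
    if (any(diff(tt$hour) != 1L))
      stop("truth hours must be contiguous per animal (", id, ")")
    n <- nrow(tt)
    sidx <- match(tt$state, .states)
    counts <- matrix(rpois(n * 4L, t(rates[sidx, , drop = FALSE])), nrow = 4L)
    tot <- colSums(counts)
    hc[[id]] <- data.frame(id = id, hour_start = tt$timestamp,
                           n_foraging = as.integer(tot))
    if (any(tot > 0)) {
      type <- rep(rep(.foraging_types, n), as.vector(counts))
      hstart <- rep(tt$timestamp, tot)
      start <- hstart + runif(sum(tot), 0, 3600)
      dur <- runif(sum(tot), 180, 900)
      rng <- t(vapply(.type_depth_range[type], identity, numeric(2)))
      depth <- runif(sum(tot), rng[, 1], rng[, 2])
      d <- data.frame(id = id, start = start, dive_type = type,
                      max_depth_m = round(depth, 1), duration_s = round(dur))
      dl[[id]] <- d[order(d$start), ]
    }
    # blocky missingness: alternate complete/missing runs
    r <- cfg$missing_hour_rate
    has <- logical(0)
    mean_miss <- cfg$missing_run_mean_h
    mean_comp <- mean_miss * (1 - r) / max(r, 1e-12)
    avail <- runif(1) > r
    while (length(has) < n) {
      len <- 1L + rpois(1, (if (avail) mean_comp else mean_miss) - 1)
      has <- c(has, rep(avail, len)); avail <- !avail
    }
    ml[[id]] <- data.frame(id = id, hour_start = tt$timestamp,
                           has_depth_data = if (r == 0) TRUE else has[seq_len(n)])
  }
  dives <- if (length(dl)) do.call(rbind, dl) else
    data.frame(id = character(), start = as.POSIXct(character(), tz = "UTC"),
               dive_type = character(), max_depth_m = numeric(), duration_s = numeric())
  mask <- do.call(rbind, ml)
  hourly_counts <- do.call(rbind, hc)
  rownames(dives) <- rownames(mask) <- rownames(hourly_counts) <- NULL
  list(dives = dives, mask = mask, hourly_counts = hourly_counts)
}

#' Write and read the pipeline's CSV interchange tables
#'
#' Timestamps are written as ISO-8601 UTC (`2018-07-10T00:00:00Z`) and parsed
#' back to POSIXct on read.
#'
#' @param x data frame to write.
#' @param path file path.
#' @name interchange-csv
#' @return `write_table_csv()` returns `path` invisibly; `read_locations_csv()`
#'   and `read_dives_csv()` return data frames with parsed timestamps.
#' @export
write_table_csv <- function(x, path) {
  for (cl in names(x)) if (inherits(x[[cl]], "POSIXct"))
    x[[cl]] <- format(x[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

.parse_time <- function(s) {
  as.POSIXct(s, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                           "%Y-%m-%dT%H:%M:%OSZ",
                                           "%Y-%m-%d %H:%M:%S",
                                           "%Y-%m-%d %H:%M"))
}

# never errors: unparseable entries come back NA (used by validation)
.parse_time_lenient <- function(s) {
  out <- as.POSIXct(strptime(s, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  alt <- as.POSIXct(strptime(s, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  out[is.na(out)] <- alt[is.na(out)]
  out
}

#' @rdname interchange-csv
#' @export
read_locations_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- .parse_time(x$timestamp)
  x
}

#' @rdname interchange-csv
#' @export
read_dives_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if ("start" %in% names(x)) x$start <- .parse_time(x$start)
  if ("hour_start" %in% names(x)) x$hour_start <- .parse_time(x$hour_start)
  x
}

#' @rdname interchange-csv
#' @param config a [sim_config()] to serialise as `key = value` text.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  fmt <- function(v) paste(format(v, digits = 10), collapse = " ")
  lines <- c(
    paste("n_animals =", config$n_animals),
    paste("hours_per_phase =", fmt(config$hours_per_phase)),
    paste("transition_matrix =", fmt(t(config$transition_matrix))),
    paste("residency_transition_matrix =", fmt(t(config$residency_transition_matrix))),
    paste("step_mean_km =", fmt(config$step_mean_km)),
    paste("step_sd_km =", fmt(config$step_sd_km)),
    paste("angle_concentration =", fmt(config$angle_concentration)),
    paste("seed =", config$seed))
  writeLines(lines, path)
  invisible(path)
}
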