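#' Error ellipse to planar covariance
#'
#' Converts a location error ellipse (semi-major and semi-minor axes in
#' metres, orientation in degrees clockwise from north) into a 2x2 covariance
#' matrix in km^2 in the local (x = east, y = north) planar frame.  The axes
#' are treated as 1-sigma.
#'
#' @param smaj_m,smin_m semi-major and semi-minor axes (m); if `smin_m >
#'   smaj_m` the two are swapped with a warning.
#' @param orient_deg ellipse orientation, degrees clockwise from north.
#' @return a 2x2 symmetric covariance matrix (km^2).
#' @examples
#' ellipse_to_cov(50, 50, 0)       # 0.0025 * I
#' @export
ellipse_to_cov <- function(smaj_m, smin_m, orient_deg) {
  if (is.na(smaj_m) || is.na(smin_m)) stop("ellipse axes must be non-missing")
  if (smin_m > smaj_m) {
    warning("semi-minor axis exceeds semi-major; swapping")
    tmp <- smaj_m; smaj_m <- smin_m; smin_m <- tmp
  }
  if (smin_m < 0) stop("ellipse axes must be >= 0")
  a <- smaj_m / 1000; b <- smin_m / 1000
  th <- orient_deg * pi / 180
  u <- c(sin(th), cos(th))         # major-axis direction in (east, north)
  w <- c(cos(th), -sin(th))
  a^2 * tcrossprod(u) + b^2 * tcrossprod(w)
}

# keep (beta, sigma) inside the region where the hour-scale discretisation is
# well conditioned; the bounds are far outside any biologically plausible fit
.clamp_beta_sigma <- function(log_par) {
  c(min(max(exp(log_par[1]), 1e-4), 1e3),
    min(max(exp(log_par[2]), 1e-6), 1e4))
}

# vectorised ellipse -> (var_x, var_y, cov_xy) in km^2
.ellipse_cov_cols <- function(smaj_m, smin_m, orient_deg) {
  a <- smaj_m / 1000; b <- smin_m / 1000
  th <- orient_deg * pi / 180
  s <- sin(th); c <- cos(th)
  data.frame(var_x = a^2 * s^2 + b^2 * c^2,
             var_y = a^2 * c^2 + b^2 * s^2,
             cov_xy = (a^2 - b^2) * s * c)
}

# project one animal's QC-passed segments into its local planar frame
.project_animal <- function(track) {
  ctr <- .centroid_lonlat(track$lon, track$lat)
  p <- aeqd_project(track$lon, track$lat, ctr["lon"], ctr["lat"])
  cv <- .ellipse_cov_cols(track$smaj_m, track$smin_m, track$orient_deg)
  out <- cbind(track[c("id", "segment", "timestamp")], p, cv)
  attr(out, "proj_centre") <- ctr
  out
}

#' Fit a continuous-time correlated random walk to a track segment
#'
#' Maximum-likelihood fit of the integrated Ornstein-Uhlenbeck velocity model
#' to irregularly timed planar observations with per-fix error covariances.
#' The x and y processes share the velocity autocorrelation decay `beta`
#' (1/h) and diffusion `sigma` (km h^-3/2); the exact Gaussian likelihood is
#' evaluated by Kalman filtering and maximised over (log beta, log sigma) by
#' BFGS (relative tolerance 1e-8, at most 500 iterations).  The filter prior
#' is centred on the first observation with a weak position variance and zero
#' velocity with a large velocity variance.
#'
#' @param segment data frame with columns `timestamp` (POSIXct), `x`, `y`
#'   (km) and `var_x`, `var_y`, `cov_xy` (km^2), as produced internally from
#'   QC-passed segments; timestamps strictly increasing.
#' @param init optional named vector `c(beta=, sigma=)` of starting values.
#' @param p0_pos,p0_vel prior variances for the initial position (km^2) and
#'   velocity ((km/h)^2).
#' @return an object of class `ctcrw` with components `beta`, `sigma`,
#'   `loglik`, `loglik_init`, `convergence`, `boundary` (TRUE when the
#'   diffusion collapsed toward zero, e.g. a stationary animal), and the data
#'   needed by [predict.ctcrw()].
#' @seealso [predict.ctcrw()], [interpolate_hourly()]
#' @export
fit_ctcrw <- function(segment, init = NULL, p0_pos = 100, p0_vel = 25) {
  n <- nrow(segment)
  if (n < 2) stop("CTCRW fit needs at least 2 locations")
  t_h <- as.numeric(segment$timestamp) / 3600
  if (any(diff(t_h) <= 0)) stop("timestamps must be strictly increasing")
  obs <- cbind(segment$x, segment$y)
  R <- cbind(segment$var_x, segment$var_y, segment$cov_xy)
  has <- rep(1L, n)

  if (is.null(init)) {
    v_emp <- sqrt(sum((obs[n, ] - obs[1, ])^2)) / max(t_h[n] - t_h[1], 1)
    d <- sqrt(diff(obs[, 1])^2 + diff(obs[, 2])^2) / diff(t_h)
    v_emp <- max(v_emp, stats::median(d), 0.1)
    init <- c(beta = 1, sigma = v_emp * sqrt(2))
  }
  nll <- function(par) {
    b <- .clamp_beta_sigma(par)[1]; s <- .clamp_beta_sigma(par)[2]
    out <- tryCatch(.ctcrw_kalman(t_h, has, obs, R, b, s, p0_pos, p0_vel, FALSE),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$loglik)) return(1e10)
    -out$loglik
  }
  par0 <- log(unname(init[c("beta", "sigma")]))
  ll0 <- -nll(par0)
  opt <- optim(par0, nll, method = "BFGS",
               control = list(reltol = 1e-8, maxit = 500))
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("CTCRW optimizer failed on segment ",
         if (!is.null(segment$segment)) segment$segment[1] else "<unnamed>",
         " (code ", opt$convergence, ")")
  cl <- .clamp_beta_sigma(opt$par)
  beta <- cl[1]; sigma <- cl[2]
  structure(list(beta = beta, sigma = sigma,
                 loglik = -opt$value, loglik_init = ll0,
                 convergence = opt$convergence,
                 boundary = sigma < 1e-3,
                 p0_pos = p0_pos, p0_vel = p0_vel,
                 t_h = t_h, obs = obs, R = R,
                 segment_id = if (!is.null(segment$segment)) segment$segment[1] else NA_character_,
                 id = if (!is.null(segment$id)) segment$id[1] else NA_character_),
            class = "ctcrw")
}

#' @export
print.ctcrw <- function(x, ...) {
  cat("Continuous-time correlated random walk fit\n")
  cat(sprintf("  segment: %s (%d fixes, %.1f h)\n", x$segment_id,
              nrow(x$obs), diff(range(x$t_h))))
  cat(sprintf("  beta  = %.4g 1/h\n  sigma = %.4g km/h^1.5\n", x$beta, x$sigma))
  cat(sprintf("  logLik %.3f (%.3f at start)%s\n", x$loglik, x$loglik_init,
              if (x$boundary) "; sigma at boundary (near-stationary track)" else ""))
  invisible(x)
}

#' @export
coef.ctcrw <- function(object, ...) c(beta = object$beta, sigma = object$sigma)

#' @export
logLik.ctcrw <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' Predict hourly positions from a fitted CTCRW
#'
#' Runs the fixed-interval (RTS) smoother over the union of observation times
#' and every whole hour inside the segment's span, and returns the smoothed
#' positions and prediction variances at the hour marks.  No extrapolation
#' beyond the segment.
#'
#' @param object a fitted [fit_ctcrw()] model.
#' @param ... unused.
#' @return data frame with `t_h` (hours since epoch), `timestamp`, `x`, `y`
#'   (km), `var_x`, `var_y` (km^2); zero rows (with a warning) when the
#'   segment contains no interior whole hour.
#' @export
predict.ctcrw <- function(object, ...) {
  t_h <- object$t_h
  h0 <- ceiling(t_h[1] - 1e-9); h1 <- floor(t_h[length(t_h)] + 1e-9)
  hours <- if (h0 > h1) numeric(0) else seq(h0, h1)
  if (!length(hours)) {
    warning("segment ", object$segment_id, " spans no whole hour; no predictions")
    return(data.frame(t_h = numeric(0), timestamp = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(0), y = numeric(0),
                      var_x = numeric(0), var_y = numeric(0)))
  }
  new <- hours[vapply(hours, function(h) min(abs(h - t_h)) > 1e-9, logical(1))]
  t_all <- sort(c(t_h, new))
  has <- as.integer(t_all %in% t_h)
  idx <- match(round(t_h, 9), round(t_all, 9))
  n_all <- length(t_all)
  obs <- matrix(0, n_all, 2); R <- matrix(0, n_all, 3)
  obs[idx, ] <- object$obs; R[idx, ] <- object$R
  sm <- .ctcrw_kalman(t_all, has, obs, R, object$beta, object$sigma,
                      object$p0_pos, object$p0_vel, TRUE)
  at <- vapply(hours, function(h) which.min(abs(t_all - h)), integer(1))
  data.frame(t_h = hours,
             timestamp = as.POSIXct(hours * 3600, origin = "1970-01-01", tz = "UTC"),
             x = sm$x[at], y = sm$y[at],
             var_x = sm$var_x[at], var_y = sm$var_y[at])
}

#' Hourly CTCRW interpolation of all QC-passed segments
#'
#' Projects each animal's QC-passed track into a local azimuthal equidistant
#' frame centred on its track centroid, fits a CTCRW per segment (or one
#' shared fit per animal), and predicts positions at every whole hour inside
#' each segment.  Predictions implying speeds above `speed_flag_ms` between
#' consecutive hourly positions are flagged (mirroring a visual check that
#' modelled tracks require no unrealistic speeds).
#'
#' @param segments segmented QC output from [qc_track()].
#' @param share_params fit one (beta, sigma) per animal across its segments
#'   instead of per segment.
#' @param speed_flag_ms hourly-speed sanity threshold (m/s).
#' @return list with `hourly` (data frame: `id`, `segment`, `timestamp`,
#'   `x_km`, `y_km`, `var_x`, `var_y`, `lon`, `lat`, `speed_flag`) and
#'   `params` (per-fit report: beta, sigma, loglik, boundary flag, n fixes).
#' @export
interpolate_hourly <- function(segments, share_params = FALSE,
                               speed_flag_ms = 5) {
  stopifnot(nrow(segments) > 0)
  hr_list <- list(); par_list <- list()
  for (id in unique(segments$id)) {
    tr <- segments[segments$id == id, , drop = FALSE]
    proj <- .project_animal(tr)
    ctr <- attr(proj, "proj_centre")
    segs <- split(proj, proj$segment)
    fits <- if (share_params) .fit_ctcrw_shared(segs) else lapply(segs, fit_ctcrw)
    for (sid in names(fits)) {
      f <- fits[[sid]]
      pr <- suppressWarnings(predict(f))
      par_list[[paste(id, sid)]] <- data.frame(
        id = id, segment = sid, n = nrow(f$obs),
        beta = f$beta, sigma = f$sigma, loglik = f$loglik,
        boundary = f$boundary)
      if (!nrow(pr)) next
      ll <- aeqd_unproject(pr$x, pr$y, ctr["lon"], ctr["lat"])
      sp <- c(NA, sqrt(diff(pr$x)^2 + diff(pr$y)^2))   # km/h on a 1 h grid
      hr_list[[paste(id, sid)]] <- data.frame(
        id = id, segment = sid, timestamp = pr$timestamp,
        x_km = pr$x, y_km = pr$y, var_x = pr$var_x, var_y = pr$var_y,
        lon = ll$lon, lat = ll$lat,
        speed_flag = !is.na(sp) & sp > speed_flag_ms * 3.6)
    }
  }
  hourly <- do.call(rbind, hr_list)
  params <- do.call(rbind, par_list)
  rownames(hourly) <- rownames(params) <- NULL
  hourly <- hourly[order(hourly$id, hourly$timestamp), , drop = FALSE]
  list(hourly = hourly, params = params)
}

# one (beta, sigma) per animal: maximise the summed segment likelihoods
.fit_ctcrw_shared <- function(segs) {
  prep <- lapply(segs, function(s) {
    list(t_h = as.numeric(s$timestamp) / 3600,
         obs = cbind(s$x, s$y), R = cbind(s$var_x, s$var_y, s$cov_xy))
  })
  nll <- function(par) {
    b <- .clamp_beta_sigma(par)[1]; s <- .clamp_beta_sigma(par)[2]
    tot <- 0
    for (p in prep) {
      out <- tryCatch(.ctcrw_kalman(p$t_h, rep(1L, length(p$t_h)), p$obs, p$R,
                                    b, s, 100, 25, FALSE),
                      error = function(e) NULL)
      if (is.null(out) || !is.finite(out$loglik)) return(1e10)
      tot <- tot - out$loglik
    }
    tot
  }
  opt <- optim(c(0, log(3)), nll, method = "BFGS",
               control = list(reltol = 1e-8, maxit = 500))
  cl <- .clamp_beta_sigma(opt$par)
  beta <- cl[1]; sigma <- cl[2]
  lapply(segs, function(s) {
    f <- list(beta = beta, sigma = sigma, loglik = -opt$value,
              loglik_init = NA_real_, convergence = opt$convergence,
              boundary = sigma < 1e-3, p0_pos = 100, p0_vel = 25,
              t_h = as.numeric(s$timestamp) / 3600,
              obs = cbind(s$x, s$y), R = cbind(s$var_x, s$var_y, s$cov_xy),
              segment_id = s$segment[1], id = s$id[1])
    class(f) <- "ctcrw"
    f
  })
}
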