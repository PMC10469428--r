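# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written from the model definitions (enumeration, dense
# linear-Gaussian algebra) and share no code with the package's recursions.

# --- brute-force HMM likelihood by enumeration over all state paths ---

oracle_vm_dens <- function(x, kappa) {
  exp(kappa * cos(x)) / (2 * pi * besselI(kappa, 0))
}

oracle_emission <- function(params, step, turn) {
  vapply(1:2, function(s) {
    mu <- params$step_mean[s]; sdv <- params$step_sd[s]
    d <- dgamma(step, shape = (mu / sdv)^2, rate = mu / sdv^2)
    if (!is.na(turn)) d <- d * oracle_vm_dens(turn, params$kappa[s])
    d
  }, numeric(1))
}

# likelihood of one segment by summing over all 2^n paths
oracle_segment_lik <- function(params, step, turn, delta) {
  n <- length(step)
  G <- params$Gamma
  dens <- t(vapply(seq_len(n), function(t)
    oracle_emission(params, step[t], turn[t]), numeric(2)))
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- delta[s[1]] * dens[1, s[1]]
    if (n > 1) for (t in 2:n) p <- p * G[s[t - 1], s[t]] * dens[t, s[t]]
    tot <- tot + p
  }
  tot
}

oracle_forward_ll <- function(params, series) {
  G <- params$Gamma
  delta <- if (is.numeric(params$delta)) params$delta else if (identical(params$delta, "uniform"))
    c(0.5, 0.5) else c(G[2, 1], G[1, 2]) / (G[1, 2] + G[2, 1])
  sum(vapply(split(seq_len(nrow(series)), series$segment), function(i) {
    log(oracle_segment_lik(params, series$step_km[i], series$turn_rad[i], delta))
  }, numeric(1)))
}

# --- dense joint-Gaussian likelihood for the integrated-OU position model ---

oracle_iou_T <- function(dt, beta) {
  e <- exp(-beta * dt)
  Tax <- matrix(c(1, 0, (1 - e) / beta, e), 2, 2)
  kronecker(diag(2), Tax)        # state ordering (x, vx, y, vy)
}

oracle_iou_Q <- function(dt, beta, sigma) {
  e <- exp(-beta * dt); e2 <- exp(-2 * beta * dt)
  q11 <- sigma^2 / beta^2 * (dt - 2 * (1 - e) / beta + (1 - e2) / (2 * beta))
  q12 <- sigma^2 * (1 - e)^2 / (2 * beta^2)
  q22 <- sigma^2 * (1 - e2) / (2 * beta)
  Qax <- matrix(c(q11, q12, q12, q22), 2, 2)
  kronecker(diag(2), Qax)
}

# joint log-density of the 2n observed coordinates under the model with prior
# state N((y1x, 0, y1y, 0), diag(p0_pos, p0_vel, p0_pos, p0_vel)) at t_1
oracle_ctcrw_ll <- function(t_h, obs, R, beta, sigma,
                            p0_pos = 100, p0_vel = 25) {
  n <- length(t_h)
  H <- rbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  m0 <- c(obs[1, 1], 0, obs[1, 2], 0)
  P0 <- diag(c(p0_pos, p0_vel, p0_pos, p0_vel))
  # state moments and cross-covariances at observation times
  V <- vector("list", n)      # Var(s_i)
  M <- vector("list", n)      # E(s_i)
  V[[1]] <- P0; M[[1]] <- m0
  for (i in 2:n) {
    dt <- t_h[i] - t_h[i - 1]
    Tt <- oracle_iou_T(dt, beta)
    V[[i]] <- Tt %*% V[[i - 1]] %*% t(Tt) + oracle_iou_Q(dt, beta, sigma)
    M[[i]] <- Tt %*% M[[i - 1]]
  }
  S <- matrix(0, 2 * n, 2 * n)
  mu <- numeric(2 * n)
  for (i in 1:n) {
    mu[(2 * i - 1):(2 * i)] <- H %*% M[[i]]
    for (j in i:n) {
      Cij <- if (i == j) V[[i]] else V[[i]] %*% t(oracle_iou_T(t_h[j] - t_h[i], beta))
      blk <- H %*% Cij %*% t(H)
      S[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <- blk
      S[(2 * j - 1):(2 * j), (2 * i - 1):(2 * i)] <- t(blk)
    }
    Ri <- matrix(c(R[i, 1], R[i, 3], R[i, 3], R[i, 2]), 2, 2)
    S[(2 * i - 1):(2 * i), (2 * i - 1):(2 * i)] <-
      S[(2 * i - 1):(2 * i), (2 * i - 1):(2 * i)] + Ri
  }
  y <- as.vector(t(obs))
  L <- chol(S)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -length(y) / 2 * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# run the package's Kalman likelihood on raw arrays (via the internal entry
# point, same one fit_ctcrw maximises)
pkg_ctcrw_ll <- function(t_h, obs, R, beta, sigma, p0_pos = 100, p0_vel = 25) {
  movestates:::.ctcrw_kalman(t_h, rep(1L, length(t_h)), obs, R, beta, sigma,
                             p0_pos, p0_vel, FALSE)$loglik
}

# --- small builders ---

loc_row <- function(id = "A", timestamp, lon = 0, lat = 70, source = "Argos",
                    n_sat = NA, residual = NA, smaj_m = 200, smin_m = 100,
                    orient_deg = 0) {
  data.frame(id = id, timestamp = as.POSIXct(timestamp, tz = "UTC"),
             lon = lon, lat = lat, source = source, n_sat = n_sat,
             residual = residual, smaj_m = smaj_m, smin_m = smin_m,
             orient_deg = orient_deg)
}

random_series <- function(n_steps, seed) {
  p <- hmm_params(step_mean = c(runif(1, 0.5, 2), runif(1, 3, 6)),
                  step_sd = runif(2, 0.5, 2), kappa = c(runif(1, 0, 2), runif(1, 5, 15)),
                  Gamma = {
                    g12 <- runif(1, 0.05, 0.4); g21 <- runif(1, 0.05, 0.4)
                    matrix(c(1 - g12, g21, g12, 1 - g21), 2, 2)
                  })
  list(params = p, series = simulate_hmm_series(p, n_steps, seed = seed))
}

# simulate irregular fixes from the exact IOU discretisation
sim_iou_track <- function(n, beta, sigma, dt_range = c(0.3, 1.5),
                          err_km = 0.05, seed = 1) {
  set.seed(seed)
  t_h <- cumsum(c(0, runif(n - 1, dt_range[1], dt_range[2])))
  s <- c(0, 0, 0, 0)
  X <- matrix(0, n, 2)
  for (i in 2:n) {
    dt <- t_h[i] - t_h[i - 1]
    Tt <- oracle_iou_T(dt, beta)
    Q <- oracle_iou_Q(dt, beta, sigma)
    s <- as.vector(Tt %*% s) + as.vector(t(chol(Q + 1e-12 * diag(4))) %*% rnorm(4))
    X[i, ] <- s[c(1, 3)]
  }
  obs <- X + matrix(rnorm(2 * n, 0, err_km), n, 2)
  data.frame(timestamp = as.POSIXct("2018-08-01", tz = "UTC") + t_h * 3600,
             x = obs[, 1], y = obs[, 2],
             var_x = err_km^2, var_y = err_km^2, cov_xy = 0)
}

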