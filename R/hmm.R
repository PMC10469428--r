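#' Step lengths and turning angles from hourly positions
#'
#' Computes, per track segment, the planar step length (km) between
#' consecutive hourly positions and the signed turning angle (change in
#' heading, wrapped into (-pi, pi]).  Steps and angles are never computed
#' across segment boundaries.  Each series row is attached to the hourly
#' location at the start of its step; the first step of a segment has an
#' undefined turning angle (`NA`).  Steps below 1e-6 km are floored at 1e-6
#' km so that gamma densities with shape < 1 stay finite on the
#' continuous-valued interpolated positions.
#'
#' @param hourly hourly-location data frame from [interpolate_hourly()]
#'   (columns `id`, `segment`, `timestamp`, `x_km`, `y_km`).
#' @return data frame of class `step_series`: `id`, `segment`, `timestamp`,
#'   `step_km`, `turn_rad`, and attribute `hourly_row` mapping each row to
#'   its source row in `hourly`.  Segments with fewer than 2 locations are
#'   skipped with a warning.
#' @export
steps_and_angles <- function(hourly) {
  out <- list(); rows <- list()
  for (sid in unique(hourly$segment)) {
    i <- which(hourly$segment == sid)
    if (length(i) < 2) {
      warning("segment ", sid, " has < 2 locations; skipped")
      next
    }
    h <- hourly[i, ]
    dx <- diff(h$x_km); dy <- diff(h$y_km)
    step <- pmax(sqrt(dx^2 + dy^2), 1e-6)
    heading <- atan2(dy, dx)
    turn <- c(NA, .wrap_angle(diff(heading)))
    out[[sid]] <- data.frame(id = h$id[-nrow(h)], segment = sid,
                             timestamp = h$timestamp[-nrow(h)],
                             step_km = step, turn_rad = turn)
    rows[[sid]] <- i[-length(i)]
  }
  if (!length(out)) stop("no segment has >= 2 locations")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "hourly_row") <- unlist(rows, use.names = FALSE)
  class(res) <- c("step_series", "data.frame")
  res
}

# log von Mises density, mean 0; stable for large kappa
.dvm_log <- function(x, kappa) {
  kappa * (cos(x) - 1) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
}

#' Two-state HMM parameter set
#'
#' Bundles the emission and transition parameters of the two-state
#' (ARS/Transit) hidden Markov model: gamma step lengths parameterised by
#' (mean, sd) in km, von Mises turning angles with mean 0 and the given
#' concentrations, a 2x2 row-stochastic transition matrix, and an initial
#' distribution (`"stationary"` of Gamma, `"uniform"`, or a length-2
#' probability vector) applied at the start of every segment.
#'
#' @param step_mean,step_sd length-2 numeric (ARS, Transit), km.
#' @param kappa length-2 turning-angle concentrations.
#' @param Gamma 2x2 row-stochastic transition matrix.
#' @param delta initial state distribution specification.
#' @return a list of class `hmm_params`.
#' @export
hmm_params <- function(step_mean, step_sd, kappa,
                       Gamma = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2),
                       delta = "stationary") {
  stopifnot(length(step_mean) == 2, length(step_sd) == 2, length(kappa) == 2)
  if (any(step_mean <= 0) || any(step_sd <= 0)) stop("step parameters must be > 0")
  if (any(kappa < 0)) stop("concentrations must be >= 0")
  if (any(Gamma < 0) || any(abs(rowSums(Gamma) - 1) > 1e-8))
    stop("Gamma must be row-stochastic")
  structure(list(step_mean = unname(step_mean), step_sd = unname(step_sd),
                 kappa = unname(kappa), Gamma = unname(Gamma), delta = delta),
            class = "hmm_params")
}

.delta_vec <- function(params) {
  d <- params$delta
  if (is.numeric(d)) return(d / sum(d))
  G <- params$Gamma
  if (identical(d, "uniform")) return(c(0.5, 0.5))
  p1 <- G[2, 1] / (G[1, 2] + G[2, 1])   # stationary distribution
  c(p1, 1 - p1)
}

# n x 2 matrix of log emission densities
.emission_logdens <- function(params, series) {
  n <- nrow(series)
  ld <- matrix(0, n, 2)
  has_turn <- !is.na(series$turn_rad)
  for (s in 1:2) {
    mu <- params$step_mean[s]; sdv <- params$step_sd[s]
    ld[, s] <- suppressWarnings(
      dgamma(series$step_km, shape = (mu / sdv)^2, rate = mu / sdv^2, log = TRUE))
    ld[has_turn, s] <- ld[has_turn, s] +
      .dvm_log(series$turn_rad[has_turn], params$kappa[s])
  }
  ld
}

.segment_starts <- function(series) {
  which(!duplicated(series$segment))
}

#' Forward log-likelihood of a step series under a two-state HMM
#'
#' Scaled forward recursion per track segment (the initial distribution is
#' applied afresh at every segment start), summed over segments, so the
#' likelihood is the product over all segments of all animals.  Rows with an
#' undefined turning angle contribute their step density only.
#'
#' @param params an [hmm_params()] object.
#' @param series a `step_series` from [steps_and_angles()].
#' @return the log-likelihood (scalar).
#' @export
forward_loglik <- function(params, series) {
  if (!nrow(series)) stop("empty series")
  if (any(series$step_km <= 0))
    stop("non-positive step lengths: apply the 1e-6 km zero-step floor ",
         "(steps_and_angles does this) before evaluating the likelihood")
  ld <- .emission_logdens(params, series)
  if (any(!is.finite(ld[series$step_km > 0, ])) && any(is.nan(ld)))
    stop("non-finite emission density")
  .hmm_forward_ll(ld, .segment_starts(series), .delta_vec(params), params$Gamma)
}

#' Initial parameter sets for the multi-start fitting protocol
#'
#' `hmm_m1_init()` is the first-model starting point: step means 1 and 5 km,
#' sds 2 and 3 km, concentrations 1 (ARS) and 13 (Transit).
#' `hmm_init_protocol()` derives the follow-up starts from a converged first
#' fit: `m2` restarts at the fitted estimates, `m3`/`m4` scale the fitted
#' step and angle parameters by 0.75 and 1.25, and `m5` is the deliberately
#' extreme start using the minimum observed step length as the ARS mean and
#' the maximum as the Transit mean (a stress test that historically exposes
#' convergence to biologically meaningless optima).
#'
#' @param fit a fitted [fit_hmm()] model (for `hmm_init_protocol`).
#' @param series the step series the protocol will be run on.
#' @return a named list of [hmm_params()] starting points.
#' @export
hmm_m1_init <- function() {
  hmm_params(step_mean = c(1, 5), step_sd = c(2, 3), kappa = c(1, 13))
}

#' @rdname hmm_m1_init
#' @export
hmm_init_protocol <- function(fit, series) {
  est <- fit$params
  scale_par <- function(f) hmm_params(est$step_mean * f, est$step_sd * f,
                                      pmax(est$kappa * f, 1e-3), est$Gamma)
  m5 <- hmm_params(step_mean = c(max(min(series$step_km), 1e-3),
                                 max(series$step_km)),
                   step_sd = est$step_sd, kappa = est$kappa, Gamma = est$Gamma)
  list(m2 = hmm_params(est$step_mean, est$step_sd, est$kappa, est$Gamma),
       m3 = scale_par(0.75), m4 = scale_par(1.25), m5 = m5)
}

.pack <- function(p) {
  c(log(p$step_mean), log(p$step_sd), log(pmax(p$kappa, 1e-8)),
    qlogis(pmin(pmax(p$Gamma[1, 2], 1e-8), 1 - 1e-8)),
    qlogis(pmin(pmax(p$Gamma[2, 1], 1e-8), 1 - 1e-8)))
}

.unpack <- function(par, delta) {
  g12 <- plogis(par[7]); g21 <- plogis(par[8])
  structure(list(step_mean = exp(par[1:2]), step_sd = exp(par[3:4]),
                 kappa = exp(par[5:6]),
                 Gamma = matrix(c(1 - g12, g21, g12, 1 - g21), 2, 2),
                 delta = delta),
            class = "hmm_params")
}

# reorder states so the ARS state has the smaller step mean
.order_states <- function(p) {
  if (p$step_mean[1] <= p$step_mean[2]) return(p)
  hmm_params(rev(p$step_mean), rev(p$step_sd), rev(p$kappa),
             p$Gamma[2:1, 2:1], if (is.numeric(p$delta)) rev(p$delta) else p$delta)
}

.is_degenerate <- function(p, trans_min = 1e-4, mean_min = 0.01) {
  any(c(p$Gamma[1, 2], p$Gamma[2, 1]) < trans_min) || any(p$step_mean < mean_min)
}

#' Fit the two-state movement HMM
#'
#' Numerical maximum likelihood for the gamma/von Mises two-state HMM on step
#' lengths and turning angles, run from one or several initial parameter
#' sets.  Optimisation is BFGS on transformed parameters (log for means, sds
#' and concentrations; logit for the transition probabilities); the initial
#' state distribution follows `delta` (default: stationary distribution of
#' the transition matrix, recomputed during optimisation).  States are
#' relabelled after fitting so that ARS always has the smaller step mean.
#'
#' Every fit is screened: a fit is flagged *degenerate* when any off-diagonal
#' transition probability falls below 1e-4 or any state step mean below 0.01
#' km (the signature of convergence to a biologically meaningless optimum),
#' and the diagnostics flag *non-identical convergence* when two converged
#' non-degenerate fits disagree by more than a relative 1e-3 on any
#' parameter.  The returned model is the best (highest log-likelihood)
#' converged non-degenerate fit; if every fit is degenerate an error is
#' raised.
#'
#' @param series a `step_series` from [steps_and_angles()] (or
#'   [simulate_hmm_series()]).
#' @param init_sets a single [hmm_params()] or named list of them; default
#'   the m1 start of [hmm_m1_init()].
#' @param delta `"stationary"`, `"uniform"`, or a length-2 probability
#'   vector.
#' @param maxit,reltol optimiser controls.
#' @return an object of class `move_hmm`: `params` (fitted [hmm_params()]),
#'   `loglik`, `loglik_init`, `delta` (realised initial distribution),
#'   `diagnostics` (one row per initial set: estimates, log-likelihood,
#'   convergence/degenerate/non-identical flags), `n` (series rows), and the
#'   fitting `series`.
#' @seealso [decode()], [simulate.move_hmm()], [hmm_init_protocol()]
#' @export
fit_hmm <- function(series, init_sets = hmm_m1_init(), delta = "stationary",
                    maxit = 500, reltol = 1e-8) {
  if (inherits(init_sets, "hmm_params")) init_sets <- list(m1 = init_sets)
  if (is.null(names(init_sets)))
    names(init_sets) <- paste0("init", seq_along(init_sets))
  nll <- function(par) {
    p <- .unpack(par, delta)
    ll <- tryCatch(forward_loglik(p, series), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fits <- list()
  for (nm in names(init_sets)) {
    par0 <- .pack(init_sets[[nm]])
    ll0 <- -nll(par0)
    opt <- tryCatch(optim(par0, nll, method = "BFGS",
                          control = list(reltol = reltol, maxit = maxit)),
                    error = function(e) NULL)
    if (is.null(opt)) {
      fits[[nm]] <- list(ok = FALSE)
      next
    }
    p <- .order_states(.unpack(opt$par, delta))
    fits[[nm]] <- list(ok = TRUE, params = p, loglik = -opt$value,
                       loglik_init = ll0,
                       converged = opt$convergence == 0,
                       degenerate = .is_degenerate(p))
  }
  usable <- vapply(fits, function(f) isTRUE(f$ok) && f$converged && !f$degenerate,
                   logical(1))
  if (!any(usable))
    stop("no initial set produced a converged, non-degenerate fit")
  lls <- vapply(fits, function(f) if (isTRUE(f$ok)) f$loglik else -Inf, numeric(1))
  best <- names(which.max(replace(lls, !usable, -Inf)))
  bp <- fits[[best]]$params
  par_vec <- function(p) c(p$step_mean, p$step_sd, p$kappa,
                           p$Gamma[1, 2], p$Gamma[2, 1])
  diag_rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (!isTRUE(f$ok))
      return(data.frame(init = nm, converged = FALSE, degenerate = NA,
                        non_identical = NA, loglik = NA_real_,
                        mu_ARS = NA_real_, mu_Transit = NA_real_,
                        sd_ARS = NA_real_, sd_Transit = NA_real_,
                        kappa_ARS = NA_real_, kappa_Transit = NA_real_,
                        g_AT = NA_real_, g_TA = NA_real_))
    v <- par_vec(f$params)
    nonid <- f$converged && !f$degenerate &&
      any(abs(v - par_vec(bp)) / pmax(abs(par_vec(bp)), 1e-12) > 1e-3)
    data.frame(init = nm, converged = f$converged, degenerate = f$degenerate,
               non_identical = nonid, loglik = f$loglik,
               mu_ARS = v[1], mu_Transit = v[2], sd_ARS = v[3],
               sd_Transit = v[4], kappa_ARS = v[5], kappa_Transit = v[6],
               g_AT = v[7], g_TA = v[8])
  })
  diagnostics <- do.call(rbind, diag_rows)
  if (any(diagnostics$non_identical, na.rm = TRUE))
    warning("non-identical convergence: initial sets ",
            paste(diagnostics$init[which(diagnostics$non_identical)], collapse = ", "),
            " reached different estimates than the selected fit")
  structure(list(params = bp, loglik = fits[[best]]$loglik,
                 loglik_init = fits[[best]]$loglik_init,
                 delta = .delta_vec(bp), selected_init = best,
                 diagnostics = diagnostics, n = nrow(series), series = series),
            class = "move_hmm")
}

#' @export
print.move_hmm <- function(x, ...) {
  p <- x$params
  cat("Two-state movement HMM (ARS / Transit)\n")
  cat(sprintf("  %d steps, logLik %.2f (init %s)\n", x$n, x$loglik, x$selected_init))
  m <- coef(x)
  print(round(m, 3))
  invisible(x)
}

#' @export
coef.move_hmm <- function(object, ...) {
  p <- object$params
  rbind(ARS = c(step_mean = p$step_mean[1], step_sd = p$step_sd[1],
                kappa = p$kappa[1], `P(stay)` = p$Gamma[1, 1]),
        Transit = c(step_mean = p$step_mean[2], step_sd = p$step_sd[2],
                    kappa = p$kappa[2], `P(stay)` = p$Gamma[2, 2]))
}

#' @export
logLik.move_hmm <- function(object, ...) {
  structure(object$loglik, df = 8, nobs = object$n, class = "logLik")
}

#' @export
summary.move_hmm <- function(object, ...) {
  cat("Two-state movement HMM\n\nState parameters:\n")
  print(round(coef(object), 4))
  cat("\nTransition matrix:\n")
  print(round(object$params$Gamma, 4))
  cat(sprintf("\nInitial distribution (per segment): %.3f / %.3f\n",
              object$delta[1], object$delta[2]))
  cat(sprintf("logLik %.2f on %d steps\n", object$loglik, object$n))
  cat("\nMulti-start diagnostics:\n")
  print(object$diagnostics, digits = 4)
  invisible(object)
}

#' Simulate a step series from HMM parameters
#'
#' Draws state sequences from the Markov chain (initial distribution applied
#' at each segment start) and emits gamma step lengths and von Mises turning
#' angles; the first row of each segment has an undefined angle, as in a real
#' series.  `simulate()` on a fitted model delegates here with the fitted
#' parameters.
#'
#' @param params an [hmm_params()] object.
#' @param segment_lengths integer vector: number of steps per simulated
#'   segment.
#' @param seed optional integer seed.
#' @param ids optional animal id per segment (recycled).
#' @return a `step_series` data frame with an extra `state` column carrying
#'   the simulated truth.
#' @export
simulate_hmm_series <- function(params, segment_lengths, seed = NULL,
                                ids = "sim") {
  if (!is.null(seed)) set.seed(seed)
  delta <- .delta_vec(params)
  ids <- rep_len(ids, length(segment_lengths))
  out <- vector("list", length(segment_lengths))
  for (k in seq_along(segment_lengths)) {
    n <- segment_lengths[k]
    s <- integer(n)
    s[1] <- 1L + (runif(1) >= delta[1])
    if (n > 1) for (t in 2:n) s[t] <- 1L + (runif(1) >= params$Gamma[s[t - 1], 1])
    mu <- params$step_mean[s]; sdv <- params$step_sd[s]
    step <- rgamma(n, shape = (mu / sdv)^2, rate = mu / sdv^2)
    turn <- rep(NA_real_, n)
    if (n > 1) for (t in 2:n) turn[t] <- rvonmises0(1, params$kappa[s[t]])
    out[[k]] <- data.frame(id = ids[k], segment = sprintf("%s_s%03d", ids[k], k),
                           timestamp = as.POSIXct("2018-07-10", tz = "UTC") + 3600 * seq_len(n),
                           step_km = pmax(step, 1e-6), turn_rad = turn,
                           state = .states[s])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("step_series", "data.frame")
  res
}

#' @rdname simulate_hmm_series
#' @param object a fitted `move_hmm`.
#' @param nsim number of independent series to simulate.
#' @param ... unused.
#' @export
simulate.move_hmm <- function(object, nsim = 1, seed = NULL,
                              segment_lengths = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(segment_lengths))
    segment_lengths <- as.vector(table(object$series$segment))
  sims <- lapply(seq_len(nsim), function(i)
    simulate_hmm_series(object$params, segment_lengths,
                        ids = sprintf("sim%02d", i)))
  if (nsim == 1) sims[[1]] else sims
}

#' Posterior state probabilities and labels
#'
#' Forward-backward posterior marginals for each series row under the fitted
#' model, with the hard label `ARS`/`Transit` assigned only when the larger
#' posterior probability reaches `threshold` (default 0.9); otherwise the row
#' is labelled `Uncertain` (it keeps its probabilities but is excluded by the
#' downstream summaries).
#'
#' @param fit a fitted `move_hmm` (or an [hmm_params()] object).
#' @param series a `step_series`; defaults to the series the model was
#'   fitted to.
#' @param threshold posterior probability needed for a hard label.
#' @return `series` with added columns `P_ARS`, `P_Transit`, `label`.
#' @export
decode <- function(fit, series = NULL, threshold = 0.9) {
  params <- if (inherits(fit, "move_hmm")) fit$params else fit
  if (is.null(series)) series <- fit$series
  ld <- .emission_logdens(params, series)
  delta <- .delta_vec(params)
  G <- params$Gamma
  n <- nrow(series)
  starts <- .segment_starts(series)
  ends <- c(starts[-1] - 1L, n)
  post <- matrix(NA_real_, n, 2)
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- ends[k]
    m <- i1 - i0 + 1L
    d <- exp(ld[i0:i1, , drop = FALSE] -
               apply(ld[i0:i1, , drop = FALSE], 1, max))
    al <- matrix(0, m, 2); be <- matrix(0, m, 2)
    a <- delta * d[1, ]; al[1, ] <- a / sum(a)
    if (m > 1) for (t in 2:m) {
      a <- (al[t - 1, ] %*% G) * d[t, ]
      al[t, ] <- a / sum(a)
    }
    be[m, ] <- 1
    if (m > 1) for (t in (m - 1):1) {
      b <- G %*% (d[t + 1, ] * be[t + 1, ])
      be[t, ] <- b / sum(b)
    }
    pp <- al * be
    post[i0:i1, ] <- pp / rowSums(pp)
  }
  series$P_ARS <- post[, 1]
  series$P_Transit <- post[, 2]
  pmax_ <- pmax(post[, 1], post[, 2])
  series$label <- ifelse(pmax_ < threshold, "Uncertain",
                         ifelse(post[, 1] >= post[, 2], "ARS", "Transit"))
  series
}

#' Decode hourly locations
#'
#' Convenience wrapper: builds the step series from hourly CTCRW positions,
#' computes posterior state probabilities under the fitted model, and joins
#' them back onto the hourly locations.  The last location of each segment
#' originates no step and is dropped.
#'
#' @param fit a fitted `move_hmm`.
#' @param hourly hourly locations from [interpolate_hourly()].
#' @param threshold posterior probability needed for a hard label.
#' @return the matched rows of `hourly` with `P_ARS`, `P_Transit`, `label`.
#' @export
decode_locations <- function(fit, hourly, threshold = 0.9) {
  series <- steps_and_angles(hourly)
  dec <- decode(fit, series, threshold)
  out <- hourly[attr(series, "hourly_row"), , drop = FALSE]
  out$P_ARS <- dec$P_ARS
  out$P_Transit <- dec$P_Transit
  out$label <- dec$label
  rownames(out) <- NULL
  out
}

#' @export
predict.move_hmm <- function(object, newdata = NULL, threshold = 0.9, ...) {
  decode(object, series = newdata, threshold = threshold)
}
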