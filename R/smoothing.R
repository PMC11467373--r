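# Time-series smoothing of per-node RSS series and coordinate series:
# cubic smoothing splines with GCV, and a local-level state-space model
# (random-walk level + observation noise) estimated by maximum likelihood
# and smoothed with the fixed-interval Kalman smoother.
#
# Series are plain lists: list(times, values, regular, step). On a regular
# series `values` may contain NA for missing slots.

#' Construct a series
#'
#' @param times numeric, strictly increasing, seconds.
#' @param values numeric, same length (dB or metres).
#' @param regular logical; `TRUE` if `times` form an arithmetic grid.
#' @param step grid increment in seconds when `regular`.
#' @return a `gl_series` list.
#' @export
gl_series <- function(times, values, regular = FALSE, step = NA_real_) {
  stopifnot(length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("series times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 regular = regular, step = step, smoothed = FALSE),
            class = "gl_series")
}

#' Put a series on a regular time grid
#'
#' Builds the grid `t_min, t_min + step, ...` spanning the observation
#' window and assigns every observation to its nearest grid slot. When two
#' observations collide in one slot the strongest value is kept for RSS
#' (`collision = "max"`) or the first for coordinates
#' (`collision = "first"`). Untouched slots are `NA`.
#'
#' @param series a [gl_series()].
#' @param step grid increment, seconds (> 0); typically the tag's nominal
#'   emission interval.
#' @param collision `"max"` or `"first"`.
#' @return a regular [gl_series()] with explicit missing slots.
#' @export
regularize_series <- function(series, step, collision = c("max", "first")) {
  stopifnot(step > 0)
  collision <- match.arg(collision)
  n <- length(series$times)
  if (n == 0) return(gl_series(numeric(0), numeric(0), TRUE, step))
  t0 <- series$times[1]
  n_slots <- floor((series$times[n] - t0) / step) + 1
  grid <- t0 + (seq_len(n_slots) - 1) * step
  slot <- round((series$times - t0) / step) + 1
  slot <- pmin(pmax(slot, 1L), n_slots)
  vals <- rep(NA_real_, n_slots)
  for (k in seq_len(n)) {
    s <- slot[k]; v <- series$values[k]
    if (is.na(vals[s])) {
      vals[s] <- v
    } else if (collision == "max" && v > vals[s]) {
      vals[s] <- v
    }
  }
  out <- gl_series(grid, vals, regular = TRUE, step = step)
  attr(out, "slot_of_obs") <- slot
  out
}

#' Cubic smoothing spline with GCV penalty selection
#'
#' Fits `stats::smooth.spline` with generalised cross-validation and
#' evaluates the fit at the input times. Series with fewer than
#' `min_points` observed values cannot be smoothed and are returned
#' unchanged with `smoothed = FALSE`.
#'
#' @param series a [gl_series()] (missing values allowed; they are
#'   ignored for fitting and left missing).
#' @param min_points minimum observed points to attempt smoothing
#'   (default 5).
#' @return a [gl_series()] with `smoothed` flag set accordingly.
#' @export
smooth_spline_series <- function(series, min_points = 5) {
  obs <- which(!is.na(series$values))
  if (length(obs) < min_points || length(unique(series$times[obs])) < 4)
    return(series)
  fit <- stats::smooth.spline(series$times[obs], series$values[obs],
                              cv = FALSE)  # GCV
  out <- series
  out$values[obs] <- stats::predict(fit, series$times[obs])$y
  out$smoothed <- TRUE
  out
}

# Kalman filter for the local-level model y_t = mu_t + eps, mu_t = mu_{t-1}
# + eta, with diffuse initialisation of the level. Returns -loglik pieces
# and the filtered moments needed by the smoother.
.ll_filter <- function(y, s2_level, s2_obs) {
  n <- length(y)
  a <- 0; P <- 1e7 * max(stats::var(y, na.rm = TRUE), 1)  # diffuse prior
  at <- numeric(n); Pt <- numeric(n)   # predicted state moments
  ll <- 0; nobs <- 0
  first_seen <- FALSE
  for (t in seq_len(n)) {
    at[t] <- a; Pt[t] <- P
    if (!is.na(y[t])) {
      Fv <- P + s2_obs
      v <- y[t] - a
      if (first_seen) {  # drop the diffuse first prediction from the loglik
        ll <- ll - 0.5 * (log(2 * pi) + log(Fv) + v^2 / Fv)
        nobs <- nobs + 1
      }
      K <- P / Fv
      a <- a + K * v
      P <- P * (1 - K)
      first_seen <- TRUE
    }
    P <- P + s2_level
    a <- a
  }
  list(loglik = ll, nobs = nobs, at = at, Pt = Pt)
}

#' Fit the local-level model by maximum likelihood
#'
#' Estimates the level-innovation and observation-noise variances of a
#' local-level state-space model on a regular series by maximising the
#' diffuse prediction-error-decomposition likelihood. Variances are
#' optimised on the log scale with BFGS, so the optimisation is
#' unconstrained while the variances stay non-negative; starting values
#' come from method-of-moments on first differences. Series with fewer
#' than `min_points` observations are flagged unfit.
#'
#' @param series a regular [gl_series()].
#' @param min_points minimum observed points (default 2).
#' @return list `sigma2_level, sigma2_obs, loglik, fitted (logical),
#'   degraded (logical)`.
#' @export
fit_local_level_ml <- function(series, min_points = 2) {
  y <- series$values
  obs <- which(!is.na(y))
  if (length(obs) < min_points)
    return(list(sigma2_level = NA_real_, sigma2_obs = NA_real_,
                loglik = NA_real_, fitted = FALSE, degraded = FALSE))
  d <- diff(y[obs])
  vd <- stats::var(d)
  if (!is.finite(vd) || vd <= 0) vd <- 1e-6
  # var(dy) = s2_level + 2 s2_obs; lag-1 autocov of dy = -s2_obs
  g1 <- if (length(d) > 2) -mean(d[-1] * d[-length(d)]) else vd / 4
  s2o0 <- min(max(g1, vd * 0.05), vd * 0.45)
  s2l0 <- max(vd - 2 * s2o0, vd * 0.05)
  par0 <- log(c(s2l0, s2o0))
  nll <- function(p) {
    s <- exp(pmin(p, 50))
    -.ll_filter(y, s[1], s[2])$loglik
  }
  opt <- try(stats::optim(par0, nll, method = "BFGS",
                          control = list(maxit = 200)), silent = TRUE)
  degraded <- inherits(opt, "try-error") || opt$convergence != 0 ||
    !is.finite(opt$value)
  par <- if (degraded) par0 else opt$par
  s <- exp(pmin(par, 50))
  list(sigma2_level = s[1], sigma2_obs = s[2],
       loglik = .ll_filter(y, s[1], s[2])$loglik,
       fitted = TRUE, degraded = degraded)
}

#' Fixed-interval Kalman smoothing of a regular series
#'
#' Runs the forward filter and backward (Rauch-Tung-Striebel) smoother of
#' the fitted local-level model over the regular grid; missing slots get
#' their smoothed predictions. If `fit` is unfit the input is returned
#' unchanged.
#'
#' @param series a regular [gl_series()].
#' @param fit output of [fit_local_level_ml()] on the same series.
#' @return a [gl_series()] of smoothed values on the same grid.
#' @export
smooth_kalman_series <- function(series, fit = fit_local_level_ml(series)) {
  if (!isTRUE(fit$fitted)) return(series)
  y <- series$values
  n <- length(y)
  s2l <- fit$sigma2_level; s2o <- max(fit$sigma2_obs, 1e-12)
  a <- 0; P <- 1e7 * max(stats::var(y, na.rm = TRUE), 1)
  af <- numeric(n); Pf <- numeric(n)  # filtered
  ap <- numeric(n); Pp <- numeric(n)  # predicted (prior)
  for (t in seq_len(n)) {
    ap[t] <- a; Pp[t] <- P
    if (!is.na(y[t])) {
      K <- P / (P + s2o)
      a <- a + K * (y[t] - a)
      P <- P * (1 - K)
    }
    af[t] <- a; Pf[t] <- P
    P <- P + s2l
  }
  sm <- numeric(n)
  sm[n] <- af[n]
  for (t in (n - 1):1) {
    if (n < 2) break
    C <- Pf[t] / (Pf[t] + s2l)  # gain toward the t+1 prior
    if (!is.finite(C)) C <- 0   # exact filtered state (0/0 case)
    sm[t] <- af[t] + C * (sm[t + 1] - af[t])
  }
  out <- series
  out$values <- sm
  out$smoothed <- TRUE
  out
}

#' Smooth a series with the chosen smoother
#'
#' Dispatcher over the smoothing axis of the workflow: `"none"` returns
#' the input untouched; `"spline"` applies the GCV cubic smoothing spline
#' at the raw observation times; `"kalman"` regularises onto a grid at
#' `step` seconds, fits the local-level model, smooths, and reads values
#' back at the original observation times (nearest grid slot). Series
#' below the per-smoother length thresholds pass through unchanged.
#'
#' @param series a [gl_series()].
#' @param method `"none"`, `"spline"` or `"kalman"`.
#' @param step regular-grid increment for the Kalman smoother, seconds.
#' @param collision collision rule passed to [regularize_series()].
#' @param min_points_spline,min_points_kalman length thresholds below
#'   which the original values are used instead.
#' @return a [gl_series()] at the original times.
#' @export
smooth_series <- function(series, method = c("none", "spline", "kalman"),
                          step = NULL, collision = "max",
                          min_points_spline = 5, min_points_kalman = 2) {
  method <- match.arg(method)
  if (method == "none" || length(series$times) == 0) return(series)
  if (method == "spline")
    return(smooth_spline_series(series, min_points = min_points_spline))
  if (is.null(step)) {
    step <- if (isTRUE(series$regular)) series$step
            else max(stats::median(diff(series$times)), 1e-6)
  }
  reg <- regularize_series(series, step, collision = collision)
  if (sum(!is.na(reg$values)) < min_points_kalman) return(series)
  fit <- fit_local_level_ml(reg, min_points = min_points_kalman)
  smr <- smooth_kalman_series(reg, fit)
  out <- series
  out$values <- smr$values[attr(reg, "slot_of_obs")]
  out$smoothed <- smr$smoothed
  out
}
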