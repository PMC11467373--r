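# Calibration of the exponential RSS-distance decay curve
#   RSS = a * exp(-S * d) + K
# where a is the intercept above the asymptote, S the decay factor (1/m)
# and K the horizontal asymptote (dB). Fitted by nonlinear least squares
# with a self-starting heuristic, globally and per node / per tag
# (two-step), with case-resampling bootstrap uncertainty.

.decay_self_start <- function(rss, distance, eps = 0.5) {
  K0 <- min(rss)
  a0 <- max(rss) - K0
  if (a0 <= 0) a0 <- 1
  # log-linearised regression of log(rss - K0 + eps) on distance
  z <- log(rss - K0 + eps)
  sl <- stats::coef(stats::lm(z ~ distance))[2]
  S0 <- max(-sl, 1e-4)
  c(a = a0, S = unname(S0), K = K0)
}

.new_decay_model <- function(cf, n, resid_se, scope = "general",
                             group_id = NA_character_, fallback = FALSE) {
  structure(list(a = unname(cf["a"]), S = unname(cf["S"]),
                 K = unname(cf["K"]), scope = scope, group_id = group_id,
                 n_points = n, resid_se = resid_se, fallback = fallback),
            class = "decay_model")
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf(
    "decay_model [%s%s]: RSS = %.3f * exp(-%.5f * d) + %.3f  (n = %d, resid SE = %.3f dB%s)\n",
    x$scope, if (is.na(x$group_id)) "" else paste0(":", x$group_id),
    x$a, x$S, x$K, x$n_points, x$resid_se,
    if (x$fallback) ", fallback" else ""))
  invisible(x)
}

#' Predicted RSS at given distances
#'
#' @param object a [fit_decay()] model.
#' @param distance distances in metres.
#' @param ... unused.
#' @return predicted RSS in dB.
#' @export
predict.decay_model <- function(object, distance, ...) {
  object$a * exp(-object$S * distance) + object$K
}

.fit_decay_nls <- function(rss, distance, start) {
  df <- data.frame(rss = rss, distance = distance)
  fit <- try(stats::nls(rss ~ a * exp(-S * distance) + K, data = df,
                        start = as.list(start), algorithm = "port",
                        lower = c(a = 1e-6, S = 1e-8, K = -Inf),
                        control = stats::nls.control(maxiter = 200,
                                                     warnOnly = FALSE)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    fit <- try(minpack.lm::nlsLM(rss ~ a * exp(-S * distance) + K, data = df,
                                 start = as.list(start),
                                 lower = c(1e-6, 1e-8, -Inf),
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200)),
               silent = TRUE)
  fit
}

#' Fit the RSS-distance decay model
#'
#' Least-squares fit of `RSS = a exp(-S d) + K`. Starting values follow a
#' self-starting asymptotic-regression heuristic: the asymptote starts at
#' the minimum RSS, the intercept at the observed range, and the decay
#' rate from a log-linearised regression (with a 0.5 dB offset to avoid
#' log of zero); the start is then refined by nonlinear least squares.
#'
#' @param points data.frame with columns `rss` (dB) and `distance` (m);
#'   extra columns (e.g. `node_id`, `tag_id`) are carried for grouping.
#' @param scope label for the fit scope (`"general"`, `"node"`, `"tag"`).
#' @param group_id group label when `scope != "general"`.
#' @param min_points minimum number of calibration points (default 10).
#' @param start optional named start vector `c(a, S, K)` overriding the
#'   self-start (used by the two-step group refits).
#' @return object of class `decay_model` with elements `a`, `S`, `K`,
#'   `scope`, `group_id`, `n_points`, `resid_se`, `fallback`.
#' @export
fit_decay <- function(points, scope = "general", group_id = NA_character_,
                      min_points = 10, start = NULL) {
  rss <- points$rss; distance <- points$distance
  ok <- is.finite(rss) & is.finite(distance)
  rss <- rss[ok]; distance <- distance[ok]
  if (length(rss) < min_points || length(unique(distance)) < 2)
    stop("decay fit needs >= ", min_points,
         " points spanning >= 2 distinct distances")
  st <- if (is.null(start)) .decay_self_start(rss, distance) else start
  fit <- .fit_decay_nls(rss, distance, st)
  if (inherits(fit, "try-error")) {
    cnd <- simpleError(paste0("decay fit did not converge: ",
                              conditionMessage(attr(fit, "condition"))))
    cnd$start <- st
    stop(cnd)
  }
  cf <- stats::coef(fit)
  resid_se <- sqrt(sum(stats::resid(fit)^2) / max(length(rss) - 3, 1))
  .new_decay_model(cf, length(rss), resid_se, scope, group_id)
}

#' Two-step per-group refit of the decay model
#'
#' Refits the decay curve independently for each node (or tag), starting
#' every group fit at the general estimates so parameters "update" from
#' the pooled fit. Groups with fewer than `min_points` points, or whose
#' fit fails, fall back to the general model with `fallback = TRUE`.
#'
#' @param points data.frame with `rss`, `distance` and the grouping column.
#' @param by grouping column name, `"node_id"` or `"tag_id"`.
#' @param general the pooled [fit_decay()] model.
#' @param min_points minimum per-group points (default 10).
#' @return named list of `decay_model` objects, one per group.
#' @export
refit_by_group <- function(points, by = c("node_id", "tag_id"), general,
                           min_points = 10) {
  by <- match.arg(by)
  scope <- if (by == "node_id") "node" else "tag"
  start <- c(a = general$a, S = general$S, K = general$K)
  groups <- split(points, points[[by]])
  out <- lapply(names(groups), function(g) {
    p <- groups[[g]]
    ok <- sum(is.finite(p$rss) & is.finite(p$distance))
    m <- if (ok >= min_points && length(unique(p$distance)) >= 2) {
      try(fit_decay(p, scope = scope, group_id = g,
                    min_points = min_points, start = start), silent = TRUE)
    } else {
      structure("too few points", class = "try-error")
    }
    if (inherits(m, "try-error"))
      m <- .new_decay_model(start, general$n_points, general$resid_se,
                            scope, g, fallback = TRUE)
    m
  })
  stats::setNames(out, names(groups))
}

#' Bootstrap uncertainty of the decay parameters
#'
#' Case-resampling bootstrap: calibration points are resampled with
#' replacement, the model refit on each replicate (started at the full-fit
#' estimates), and percentile confidence intervals taken over the
#' converged replicates. Non-convergent replicates are dropped and
#' counted; more than 20% failures attaches a warning flag.
#'
#' @param points data.frame with `rss` and `distance`.
#' @param model the full-sample [fit_decay()] model.
#' @param n_boot number of bootstrap replicates (default 999).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with `estimates` (matrix of replicate parameters), `se`
#'   (named vector), `ci` (2 x 3 matrix), `n_failed`, `unstable`
#'   (failure-rate flag) and `se_defined` (`FALSE` when `n_boot < 2`).
#' @export
bootstrap_decay <- function(points, model, n_boot = 999, seed = 1,
                            level = 0.95) {
  set.seed(seed)
  start <- c(a = model$a, S = model$S, K = model$K)
  n <- nrow(points)
  reps <- matrix(NA_real_, n_boot, 3, dimnames = list(NULL, c("a", "S", "K")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    fit <- .fit_decay_nls(points$rss[idx], points$distance[idx], start)
    if (!inherits(fit, "try-error"))
      reps[b, ] <- stats::coef(fit)[c("a", "S", "K")]
  }
  ok <- stats::complete.cases(reps)
  est <- reps[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  se_defined <- sum(ok) >= 2
  se <- if (se_defined) apply(est, 2, stats::sd)
        else stats::setNames(rep(NA_real_, 3), c("a", "S", "K"))
  ci <- apply(est, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  rownames(ci) <- c("lower", "upper")
  n_failed <- sum(!ok)
  unstable <- n_failed > 0.2 * n_boot
  if (unstable)
    warning(n_failed, "/", n_boot, " bootstrap replicates failed to converge")
  list(estimates = est, se = se, ci = ci, n_failed = n_failed,
       unstable = unstable, se_defined = se_defined)
}

#' Build calibration points from observations and a truth track
#'
#' Joins per-(relocation x node) RSS observations to the true
#' relocation-to-node Euclidean distances in the working CRS.
#'
#' @param obs output of [aggregate_rss()] (one or more trials, row-bound).
#' @param tracks relocation data.frame ([read_truth_track()] rows bound
#'   over trials).
#' @param nodes node registry from [read_nodes()].
#' @param rss_type `"max"` or `"avg"`: which aggregated RSS to calibrate.
#' @param tag_ids optional named vector mapping `trial_id` to `tag_id`
#'   (adds a `tag_id` column for per-tag refits).
#' @return data.frame `rss,distance,node_id,trial_id,reloc_idx[,tag_id]`.
#' @export
calibration_points <- function(obs, tracks, nodes, rss_type = c("max", "avg"),
                               tag_ids = NULL) {
  rss_type <- match.arg(rss_type)
  key_obs <- paste(obs$trial_id, obs$reloc_idx)
  key_trk <- paste(tracks$trial_id, tracks$reloc_idx)
  it <- match(key_obs, key_trk)
  im <- match(obs$node_id, nodes$node_id)
  ok <- !is.na(it) & !is.na(im)
  o <- obs[ok, , drop = FALSE]
  d <- sqrt((tracks$x[it[ok]] - nodes$x[im[ok]])^2 +
            (tracks$y[it[ok]] - nodes$y[im[ok]])^2)
  out <- data.frame(
    rss = if (rss_type == "max") o$rss_max else o$rss_avg,
    distance = d, node_id = o$node_id, trial_id = o$trial_id,
    reloc_idx = o$reloc_idx, stringsAsFactors = FALSE)
  if (!is.null(tag_ids)) out$tag_id <- unname(tag_ids[out$trial_id])
  out
}
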