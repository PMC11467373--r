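# Inverting fitted decay models to node-wise distance estimates and
# producing one location per relocation by one of four methods:
# multilateration over all detecting nodes, trilateration with the three
# strongest or three nearest nodes, and grouped k-means consensus.

#' Invert a decay model to an estimated distance
#'
#' Solves `rss = a exp(-S d) + K` for `d`. Reads at or below the
#' horizontal asymptote `K` are uninformative about distance and are
#' excluded (`NA`); negative solutions (reads stronger than the zero-
#' distance prediction `a + K`) are taken to be very close to the node
#' and clamped to 0 m.
#'
#' @param rss RSS values in dB (vectorised).
#' @param model a [fit_decay()] model.
#' @return estimated distances in metres; `NA` where excluded.
#' @export
invert_distance <- function(rss, model) {
  stopifnot(model$a > 0, model$S > 0)
  d <- rep(NA_real_, length(rss))
  ok <- is.finite(rss) & rss > model$K
  d[ok] <- -log((rss[ok] - model$K) / model$a) / model$S
  d[ok & d < 0] <- 0
  d
}

#' Select the nodes used for localisation
#'
#' `"all"` keeps every valid estimate; `"strongest3"` the three with the
#' highest RSS; `"nearest3"` the three smallest estimated distances. Ties
#' at the selection boundary are broken by lexicographic `node_id` and
#' counted. Relocations with fewer than 3 valid estimates are skipped
#' (returns `NULL`), never an error.
#'
#' @param est data.frame with columns `node_id`, `rss_used`, `d_hat`.
#' @param rule `"all"`, `"strongest3"` or `"nearest3"`.
#' @return the selected subset with attribute `ties_broken`, or `NULL`
#'   when fewer than 3 estimates are available.
#' @export
select_nodes <- function(est, rule = c("all", "strongest3", "nearest3")) {
  rule <- match.arg(rule)
  est <- est[is.finite(est$d_hat), , drop = FALSE]
  if (nrow(est) < 3) return(NULL)
  ties <- 0L
  if (rule != "all" && nrow(est) > 3) {
    key <- if (rule == "strongest3") -est$rss_used else est$d_hat
    ord <- order(key, est$node_id)
    est <- est[ord, , drop = FALSE]
    key <- key[ord]
    # discarded candidates tied with the last selected key
    ties <- sum(key[-(1:3)] == key[3])
    est <- est[1:3, , drop = FALSE]
  }
  attr(est, "ties_broken") <- ties
  est
}

.mlat_objective <- function(p, nx, ny, d) {
  sum((d - sqrt((p[1] - nx)^2 + (p[2] - ny)^2))^2)
}

.mlat_gradient <- function(p, nx, ny, d) {
  rx <- p[1] - nx; ry <- p[2] - ny
  r <- sqrt(rx^2 + ry^2)
  r[r < 1e-9] <- 1e-9
  w <- -2 * (d - r) / r
  c(sum(w * rx), sum(w * ry))
}

.grid_search_mlat <- function(nx, ny, d, pad = 500, res = 1) {
  gx <- seq(min(nx) - pad, max(nx) + pad, by = res)
  gy <- seq(min(ny) - pad, max(ny) + pad, by = res)
  best <- c(NA_real_, NA_real_); best_v <- Inf
  # scan row blocks to bound memory
  for (yb in split(gy, ceiling(seq_along(gy) / 256))) {
    obj <- matrix(0, length(gx), length(yb))
    for (k in seq_along(d))
      obj <- obj + (d[k] - sqrt(outer(gx - nx[k], yb - ny[k],
                                      function(a, b) a^2 + b^2)^0.5))^2
    i <- arrayInd(which.min(obj), dim(obj))
    if (obj[i] < best_v) {
      best_v <- obj[i]
      best <- c(gx[i[1]], yb[i[2]])
    }
  }
  best
}

#' Multilaterate a position from node distances
#'
#' Minimises the sum of squared differences between estimated distances
#' and point-to-node ranges, starting from the inverse-distance-weighted
#' centroid of the nodes (weights `1/(d_hat + 1)`). Quasi-Newton descent
#' with an objective tolerance of 1e-8 m and at most 200 iterations; if
#' that fails, an exhaustive 1 m grid search over the node bounding box
#' padded by 500 m is used and the result flagged unconverged. Collinear
#' node subsets are still attempted but flagged.
#'
#' @param subset data.frame with `node_id`, `d_hat` and node positions
#'   `x`, `y` (metres).
#' @return list `x_hat, y_hat, converged, collinear, objective`; `NULL`
#'   if fewer than 3 nodes.
#' @export
multilaterate <- function(subset) {
  if (is.null(subset) || nrow(subset) < 3) return(NULL)
  nx <- subset$x; ny <- subset$y; d <- subset$d_hat
  # collinearity: area of the node cloud's smallest principal axis
  sv <- svd(cbind(nx - mean(nx), ny - mean(ny)))$d
  collinear <- sv[2] < 1e-6 * max(sv[1], 1)
  w <- 1 / (d + 1)
  p0 <- c(sum(w * nx), sum(w * ny)) / sum(w)
  opt <- try(stats::optim(p0, .mlat_objective, gr = .mlat_gradient,
                          nx = nx, ny = ny, d = d, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-12,
                                         abstol = 1e-8)),
             silent = TRUE)
  if (!inherits(opt, "try-error") && opt$convergence == 0 &&
      all(is.finite(opt$par))) {
    return(list(x_hat = opt$par[1], y_hat = opt$par[2], converged = TRUE,
                collinear = collinear, objective = opt$value))
  }
  p <- .grid_search_mlat(nx, ny, d)
  if (!all(is.finite(p))) return(NULL)
  list(x_hat = p[1], y_hat = p[2], converged = FALSE, collinear = collinear,
       objective = .mlat_objective(p, nx, ny, d))
}

.choose_k_elbow <- function(wss) {
  # smallest k >= 2 whose incremental reduction from k-1 is < 10% of
  # WSS at k = 1; numerically coincident candidates collapse to k = 1
  if (length(wss) == 1 || wss[1] < 1e-9) return(1L)
  red <- -diff(wss)
  hit <- which(red < 0.1 * wss[1])
  if (length(hit)) hit[1] + 1L else length(wss)
}

#' Grouped k-means consensus localisation
#'
#' Multilaterates every subset of size >= 3 of the (at most `max_nodes`)
#' strongest-signal nodes — up to 99 candidate positions for 7 nodes —
#' then clusters the candidates with k-means and returns the centroid of
#' the largest cluster, so extreme or spatially biased candidates are
#' filtered out. k is scanned from 1 to `min(5, n_candidates - 1)` with
#' multiple restarts and chosen by an elbow rule on the within-cluster
#' sum of squares; ties in cluster size go to the cluster with the
#' smaller within-cluster sum of squares.
#'
#' @param est data.frame with `node_id`, `rss_used`, `d_hat`, `x`, `y`.
#' @param max_nodes maximum number of nodes considered (default 7).
#' @param seed RNG seed for the k-means restarts.
#' @return list `x_hat, y_hat, converged, diagnostics` where diagnostics
#'   holds `n_candidates, k_chosen, cluster_sizes, total_wss`; `NULL`
#'   when fewer than 3 valid estimates.
#' @export
grouped_kmeans_localise <- function(est, max_nodes = 7, seed = 1) {
  est <- est[is.finite(est$d_hat), , drop = FALSE]
  if (nrow(est) < 3) return(NULL)
  ord <- order(-est$rss_used, est$node_id)
  est <- est[utils::head(ord, max_nodes), , drop = FALSE]
  n <- nrow(est)
  cand <- list()
  for (size in 3:n) {
    combs <- utils::combn(n, size)
    for (c_i in seq_len(ncol(combs))) {
      m <- multilaterate(est[combs[, c_i], , drop = FALSE])
      if (!is.null(m)) cand[[length(cand) + 1]] <- c(m$x_hat, m$y_hat)
    }
  }
  if (!length(cand)) return(NULL)
  pts <- do.call(rbind, cand)
  n_cand <- nrow(pts)
  if (n_cand == 1) {
    return(list(x_hat = pts[1, 1], y_hat = pts[1, 2], converged = TRUE,
                diagnostics = list(n_candidates = 1L, k_chosen = 1L,
                                   cluster_sizes = 1L, total_wss = 0)))
  }
  kmax <- min(5, n_cand - 1)
  set.seed(seed)
  wss1 <- sum(scale(pts, scale = FALSE)^2)
  fits <- vector("list", kmax)
  wss <- numeric(kmax)
  wss[1] <- wss1
  for (k in seq_len(kmax)[-1]) {
    fits[[k]] <- suppressWarnings(
      stats::kmeans(pts, centers = k, nstart = 10, iter.max = 50))
    wss[k] <- fits[[k]]$tot.withinss
  }
  k_chosen <- .choose_k_elbow(wss)
  if (k_chosen == 1) {
    centre <- colMeans(pts)
    sizes <- n_cand
  } else {
    km <- fits[[k_chosen]]
    sizes <- km$size
    biggest <- which(sizes == max(sizes))
    if (length(biggest) > 1)
      biggest <- biggest[which.min(km$withinss[biggest])]
    centre <- km$centers[biggest, ]
    sizes <- km$size
  }
  list(x_hat = unname(centre[1]), y_hat = unname(centre[2]), converged = TRUE,
       diagnostics = list(n_candidates = n_cand, k_chosen = as.integer(k_chosen),
                          cluster_sizes = as.integer(sizes),
                          total_wss = wss[k_chosen]))
}

#' Localise every relocation of a trial
#'
#' Runs the chosen localisation method over a per-trial observation table:
#' the active RSS column is inverted through the decay model for the
#' matching scope (general, per-node or per-tag), reads at or below the
#' asymptote are excluded, relocations detected by fewer than 3 valid
#' nodes are skipped, and the remaining node sets are localised.
#'
#' @param obs observation table from [aggregate_rss()] (optionally with
#'   smoothed RSS columns), one trial.
#' @param nodes node registry from [read_nodes()].
#' @param models either a single general `decay_model` or a named list of
#'   per-group models (named by `node_id` or `tag_id`); per-tag scope uses
#'   `tag_id` to pick the model for the whole trial.
#' @param method `"all_nodes"`, `"strongest3"`, `"nearest3"` or
#'   `"grouped_kmeans"`.
#' @param rss_type `"max"` or `"avg"`.
#' @param tag_id tag of this trial (needed for per-tag scope).
#' @param seed RNG seed for the consensus method.
#' @return data.frame `trial_id,reloc_idx,method,x_hat,y_hat,n_nodes_used,
#'   converged,rss_rank_ties_broken`, one row per localisable relocation.
#' @export
localise_trial <- function(obs, nodes, models,
                           method = c("all_nodes", "strongest3", "nearest3",
                                      "grouped_kmeans"),
                           rss_type = c("max", "avg"), tag_id = NULL,
                           seed = 1) {
  method <- match.arg(method)
  rss_type <- match.arg(rss_type)
  rss_col <- if (rss_type == "max") "rss_max" else "rss_avg"
  per_group <- is.list(models) && !inherits(models, "decay_model")
  scope <- if (!per_group) "general" else models[[1]]$scope
  rows <- list()
  for (ri in unique(obs$reloc_idx)) {
    o <- obs[obs$reloc_idx == ri, , drop = FALSE]
    rss <- o[[rss_col]]
    d <- numeric(nrow(o))
    for (k in seq_len(nrow(o))) {
      mdl <- if (!per_group) models
             else if (scope == "node") models[[o$node_id[k]]]
             else models[[tag_id]]
      if (is.null(mdl)) mdl <- if (per_group) models[[1]] else models
      d[k] <- invert_distance(rss[k], mdl)
    }
    im <- match(o$node_id, nodes$node_id)
    est <- data.frame(node_id = o$node_id, rss_used = rss, d_hat = d,
                      x = nodes$x[im], y = nodes$y[im],
                      stringsAsFactors = FALSE)
    est <- est[is.finite(est$d_hat) & is.finite(est$x), , drop = FALSE]
    if (nrow(est) < 3) next
    ties <- 0L
    if (method == "grouped_kmeans") {
      loc <- grouped_kmeans_localise(est, seed = seed + ri)
      n_used <- min(nrow(est), 7L)
    } else {
      rule <- switch(method, all_nodes = "all", strongest3 = "strongest3",
                     nearest3 = "nearest3")
      sel <- select_nodes(est, rule)
      if (is.null(sel)) next
      ties <- attr(sel, "ties_broken")
      loc <- multilaterate(sel)
      n_used <- nrow(sel)
    }
    if (is.null(loc)) next
    rows[[length(rows) + 1]] <- data.frame(
      trial_id = o$trial_id[1], reloc_idx = ri, method = method,
      x_hat = loc$x_hat, y_hat = loc$y_hat, n_nodes_used = n_used,
      converged = loc$converged, rss_rank_ties_broken = ties,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(trial_id = character(0), reloc_idx = integer(0),
                      method = character(0), x_hat = numeric(0),
                      y_hat = numeric(0), n_nodes_used = integer(0),
                      converged = logical(0),
                      rss_rank_ties_broken = integer(0)))
  }
  do.call(rbind, rows)
}
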