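# Matching raw detections to ground-truth relocations and aggregating them
# into per-(relocation x node) RSS observations.

#' Match detections to the nearest relocation in time
#'
#' Each detection is assigned to the ground-truth relocation with the
#' smallest absolute time difference; assignments farther than `max_gap`
#' seconds remain unmatched (`NA`). The 10 s default absorbs reception
#' delays and mismatches between GPS and node clocks. A detection exactly
#' equidistant between two fixes goes to the earlier one.
#'
#' @param detections data.frame from [read_detections()], already filtered
#'   to the trial's tag.
#' @param track relocation data.frame from [read_truth_track()].
#' @param max_gap maximum |time difference| in seconds (strict: gaps
#'   greater than `max_gap` are unmatched).
#' @return `detections` with an added integer column `reloc_idx` (`NA`
#'   when unmatched).
#' @export
match_detections <- function(detections, track, max_gap = 10) {
  stopifnot(nrow(track) >= 1)
  if (nrow(detections) == 0) {
    detections$reloc_idx <- integer(0)
    return(detections)
  }
  tt <- as.numeric(track$timestamp)
  td <- as.numeric(detections$timestamp_utc)
  ord <- order(tt)
  tt_s <- tt[ord]
  # index of last fix at or before each detection
  lo <- findInterval(td, tt_s)
  lo_i <- pmax(lo, 1L)
  hi_i <- pmin(lo + 1L, length(tt_s))
  d_lo <- abs(td - tt_s[lo_i])
  d_hi <- abs(td - tt_s[hi_i])
  # tie (equal |dt|) goes to the earlier fix, i.e. lo wins on <=
  pick <- ifelse(lo < 1L, hi_i, ifelse(d_lo <= d_hi, lo_i, hi_i))
  gap <- pmin(ifelse(lo < 1L, Inf, d_lo), d_hi)
  idx <- track$reloc_idx[ord][pick]
  idx[gap > max_gap] <- NA_integer_
  detections$reloc_idx <- as.integer(idx)
  detections
}

.aggregate_one <- function(rss, outlier_db) {
  m_all <- mean(rss)
  keep <- abs(rss - m_all) < outlier_db  # removal rule is ">= threshold"
  if (!any(keep)) {
    list(rss_avg = m_all, n_outliers = 0L)
  } else {
    list(rss_avg = mean(rss[keep]), n_outliers = sum(!keep))
  }
}

#' Aggregate matched detections into per-(relocation x node) observations
#'
#' For every relocation/node pair the maximum RSS is taken over all
#' contributing reads, while the average RSS is recomputed after a single
#' outlier pass: reads `outlier_db` dB or more away from the plain mean
#' are removed and the survivors re-averaged (the maximum accounts for
#' signal bouncing and multipathing and is never outlier-filtered). If the
#' pass would remove every read, the plain mean is kept and no outliers
#' are counted.
#'
#' @param matched output of [match_detections()].
#' @param outlier_db outlier distance threshold in dB (default 4.33, the
#'   grid calibration value below which 95% of reads fell; comparison is
#'   `>=`).
#' @param trial_id identifier copied onto the output rows.
#' @return data.frame `trial_id,reloc_idx,node_id,rss_max,rss_avg,n_reads,
#'   n_outliers_removed`, one row per (relocation, node) with >= 1 read.
#' @export
aggregate_rss <- function(matched, outlier_db = 4.33, trial_id = NULL) {
  m <- matched[!is.na(matched$reloc_idx), , drop = FALSE]
  if (is.null(trial_id))
    trial_id <- if (nrow(m)) "trial" else character(0)
  if (!nrow(m)) {
    return(data.frame(trial_id = character(0), reloc_idx = integer(0),
                      node_id = character(0), rss_max = numeric(0),
                      rss_avg = numeric(0), n_reads = integer(0),
                      n_outliers_removed = integer(0)))
  }
  key <- interaction(m$reloc_idx, m$node_id, drop = TRUE)
  groups <- split(m$rss_db, key)
  # split() orders groups by factor level; align metadata the same way
  first_rows <- match(names(groups), as.character(key))
  meta <- m[first_rows, c("reloc_idx", "node_id")]
  agg <- lapply(groups, function(r) {
    a <- .aggregate_one(r, outlier_db)
    c(rss_max = max(r), rss_avg = a$rss_avg,
      n_reads = length(r), n_outliers = a$n_outliers)
  })
  am <- do.call(rbind, agg)
  out <- data.frame(trial_id = trial_id, reloc_idx = meta$reloc_idx,
                    node_id = meta$node_id,
                    rss_max = am[, "rss_max"], rss_avg = am[, "rss_avg"],
                    n_reads = as.integer(am[, "n_reads"]),
                    n_outliers_removed = as.integer(am[, "n_outliers"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$reloc_idx, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match and aggregate in one step
#'
#' Convenience wrapper: [match_detections()] then [aggregate_rss()].
#'
#' @inheritParams match_detections
#' @inheritParams aggregate_rss
#' @return see [aggregate_rss()].
#' @export
prep_observations <- function(detections, track, max_gap = 10,
                              outlier_db = 4.33,
                              trial_id = track$trial_id[1]) {
  aggregate_rss(match_detections(detections, track, max_gap),
                outlier_db = outlier_db, trial_id = trial_id)
}
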