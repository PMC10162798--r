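#' Compute the occupancy map
#'
#' Bins a position track onto the analysis grid (15 x 15 bins of
#' 2 x 2 cm). Bin edges are half-open with the top/right edge closed, so
#' every in-bounds position lands in exactly one bin. The origin is the
#' arena's lower-left corner; bin `[1, 1]` is the lower-left square.
#'
#' @param track A [position_track()].
#' @param n_bins Bins per side (default 15).
#' @param bin_size Bin side length in cm (default 2).
#' @return An object of class `occupancy_map`: list with `dwell` (n_bins x
#'   n_bins matrix of seconds, rows = x bins, cols = y bins), `counts`,
#'   `bin_size`, `rate`, `total_time`.
#' @export
compute_occupancy <- function(track, n_bins = 15L, bin_size = 2) {
  stopifnot(inherits(track, "position_track"))
  n_bins <- check_count(n_bins, "n_bins")
  x <- track$samples$x_cm; y <- track$samples$y_cm
  hi <- n_bins * bin_size
  bad <- which(x < 0 | x > hi | y < 0 | y > hi)
  if (length(bad))
    stop_invalid(sprintf("positions out of bounds at sample(s): %s",
                         paste(utils::head(bad, 10), collapse = ", ")))
  bx <- pmin(floor(x / bin_size), n_bins - 1L) + 1L
  by <- pmin(floor(y / bin_size), n_bins - 1L) + 1L
  counts <- matrix(tabulate(bx + n_bins * (by - 1L), n_bins * n_bins),
                   n_bins, n_bins)
  structure(list(dwell = counts / track$rate, counts = counts,
                 bin_size = bin_size, rate = track$rate,
                 total_time = length(x) / track$rate,
                 bin_index = cbind(bx, by)),
            class = "occupancy_map")
}

# align an activity vector (sampled at `rate` from `t0`) to track samples
# by nearest-sample pairing
align_activity <- function(activity, rate, t0, track) {
  idx <- round((track$samples$t_s - t0) * rate) + 1L
  idx <- pmin(pmax(idx, 1L), length(activity))
  activity[idx]
}

# isolate calcium-transient activity. Two reductions are offered:
#   "transients" - rectify at zero and zero out samples below
#                  `transient_sd` robust noise SDs (MAD)
#   "onsets"     - discrete transient detection: a unit impulse at each
#                  upward crossing of the threshold. Onsets carry no decay
#                  tail, so they localize activity in space
# `noise_scale` may be supplied so epoch-restricted maps share the
# full-session estimate.
prep_activity <- function(a, rectify = TRUE, transient_sd = 2,
                          noise_scale = NULL,
                          mode = c("transients", "onsets")) {
  mode <- match.arg(mode)
  if (is.null(noise_scale)) noise_scale <- stats::mad(a)
  thr <- transient_sd * noise_scale
  if (mode == "onsets") {
    if (!is.finite(thr) || thr <= 0) return(as.numeric(a > 0 & c(0, utils::head(a, -1)) <= 0))
    up <- a >= thr & c(-Inf, utils::head(a, -1)) < thr
    return(as.numeric(up))
  }
  if (rectify) a <- pmax(a, 0)
  if (transient_sd > 0 && is.finite(thr) && thr > 0) a[a < thr] <- 0
  a
}

#' Compute a rate map
#'
#' Mean activity per second in each spatial bin:
#' `lambda_i = (sum of activity samples in bin i) / dwell_i`. Activity is
#' paired to track samples by nearest sample and reduced to its transient
#' component first: rectified at zero and thresholded at `transient_sd`
#' robust noise SDs (extracted fluorescence fluctuates around baseline;
#' the spatial statistics are defined on the calcium transients, and the
#' sub-noise floor would otherwise dominate sparse signals).
#'
#' @param activity Numeric vector: one neuron's activity samples.
#' @param track The session [position_track()].
#' @param occ The matching [compute_occupancy()] result.
#' @param rate Sampling rate of `activity`, Hz (defaults to the track
#'   rate).
#' @param t0 Time of the first activity sample.
#' @param rectify Clamp negative activity to zero before mapping.
#' @param transient_sd Transient isolation threshold in robust (MAD) noise
#'   SDs; 0 disables thresholding.
#' @param noise_scale Optional pre-computed noise scale (activity units)
#'   overriding the MAD estimate; used to keep epoch-restricted maps on
#'   the full-session scale.
#' @param active_frac Fraction of the peak bin rate at or above which a
#'   visited bin counts as active (default 0.2).
#' @param min_dwell Minimum dwell (seconds) for a bin's rate to be
#'   defined; bins below it are flagged unvisited (`NA`). Guards against
#'   rate blow-up in barely-visited bins.
#' @param smooth_sigma Gaussian smoothing SD in bins applied to the
#'   activity-sum and dwell maps before their ratio (0 = no smoothing,
#'   the default). Smoothing suppresses isolated single-visit rate spikes
#'   while preserving coherent multi-bin fields.
#' @param activity_mode `"transients"` maps supra-threshold fluorescence;
#'   `"onsets"` maps discrete transient onsets (unit impulse at each
#'   upward threshold crossing), which carry no decay-tail smear and are
#'   preferred for localization (center-of-mass) analyses.
#' @param pre_aligned Set when `activity` is already paired one-to-one
#'   with the track samples (epoch-restricted analyses); skips
#'   nearest-sample alignment.
#' @return An object of class `rate_map`: list with `rate` (matrix,
#'   `NA` for unvisited/under-sampled bins), `lambda_mean`
#'   (occupancy-weighted mean rate), `active_bins`, `active` (logical
#'   matrix), `bin_size`.
#' @export
compute_rate_map <- function(activity, track, occ = compute_occupancy(track),
                             rate = track$rate, t0 = 0, rectify = TRUE,
                             transient_sd = 2, noise_scale = NULL,
                             active_frac = 0.2, min_dwell = 0.5,
                             smooth_sigma = 0,
                             activity_mode = c("transients", "onsets"),
                             pre_aligned = FALSE) {
  stopifnot(inherits(track, "position_track"), inherits(occ, "occupancy_map"))
  activity_mode <- match.arg(activity_mode)
  a <- if (pre_aligned) {
    if (length(activity) != nrow(track$samples))
      stop_invalid("pre-aligned activity must match the track sample count")
    activity
  } else align_activity(activity, rate, t0, track)
  if (!length(a)) stop_empty("no overlapping samples between trace and track")
  a <- prep_activity(a, rectify, transient_sd, noise_scale, activity_mode)
  nb <- nrow(occ$dwell)
  flat <- occ$bin_index[, 1] + nb * (occ$bin_index[, 2] - 1L)
  sums <- numeric(nb * nb)
  agg <- rowsum(a, flat)
  sums[as.integer(rownames(agg))] <- agg
  sum_m <- matrix(sums, nb, nb)
  dwell_m <- occ$dwell
  if (smooth_sigma > 0) {
    sum_m <- gauss_smooth(sum_m, smooth_sigma)
    dwell_m <- gauss_smooth(dwell_m, smooth_sigma)
  }
  lam <- sum_m / dwell_m
  lam[occ$counts == 0L | dwell_m < min_dwell] <- NA_real_
  p <- occ$dwell / occ$total_time
  lambda_mean <- sum(p * lam, na.rm = TRUE)
  peak <- suppressWarnings(max(lam, na.rm = TRUE))
  active <- !is.na(lam) & is.finite(peak) & peak > 0 &
    lam >= active_frac * peak
  structure(list(rate = lam, lambda_mean = lambda_mean,
                 active_bins = sum(active), active = active,
                 bin_size = occ$bin_size),
            class = "rate_map")
}

#' Skaggs-style spatial information of a rate map
#'
#' `SI = sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` over
#' visited bins, where `p_i` is occupancy probability, `lambda_i` the bin
#' rate and `lambda` the occupancy-weighted mean rate. Zero-rate bins
#' contribute zero. Nonnegative for nonnegative activity.
#'
#' @param map A [compute_rate_map()] result.
#' @param occ The matching [compute_occupancy()] result.
#' @return Spatial information in bits per activity unit.
#' @export
spatial_information <- function(map, occ) {
  stopifnot(inherits(map, "rate_map"), inherits(occ, "occupancy_map"))
  lam <- map$rate; p <- occ$dwell / occ$total_time
  ok <- !is.na(lam)
  lbar <- sum(p[ok] * lam[ok])
  if (!is.finite(lbar) || lbar <= 0)
    stop_undefined("mean rate is zero: spatial information undefined")
  rel <- lam[ok] / lbar
  terms <- ifelse(rel > 0, p[ok] * rel * log2(rel), 0)
  sum(terms)
}

# spatial information from per-bin activity sums (internal fast path used
# by the shuffle test; dwell/p fixed, activity re-summed per shuffle)
si_from_sums <- function(sums, dwell, total_time, min_dwell = 0) {
  ok <- dwell > 0 & dwell >= min_dwell
  lam <- sums[ok] / dwell[ok]
  p <- dwell[ok] / total_time
  lbar <- sum(p * lam)
  if (lbar <= 0) return(NA_real_)
  rel <- lam / lbar
  sum(ifelse(rel > 0, p * rel * log2(rel), 0))
}

#' Circular-shift shuffle test for spatial modulation
#'
#' Scores a neuron's spatial information against a null distribution built
#' by circularly shifting the activity trace in time relative to the
#' position track (preserving the trace's autocorrelation while destroying
#' its coupling to position). Shifts are drawn uniformly from
#' `[min_shift, duration - min_shift]` seconds. A neuron is spatially
#' modulated when it is eligible (active in at least `min_active_bins`
#' bins) and its observed SI exceeds the `alpha_percentile`-th percentile
#' of the shuffles.
#'
#' @inheritParams compute_rate_map
#' @param n_shuffles Number of circular shifts (default 1000).
#' @param min_shift Minimum shift in seconds (default 20).
#' @param alpha_percentile Significance percentile (default 95).
#' @param seed Integer seed for the shift draws.
#' @param min_dwell Minimum bin dwell in seconds, as in
#'   [compute_rate_map()].
#' @param min_active_bins Eligibility floor on active bins (default 3).
#' @return An object of class `spatial_info_result`: list with `si`,
#'   `shuffle_distribution`, `percentile` (of the observed SI among
#'   shuffles), `is_spatial`, `eligible`, `active_bins`, `n_shuffles`.
#' @export
shuffle_test <- function(activity, track, occ = compute_occupancy(track),
                         rate = track$rate, t0 = 0, n_shuffles = 1000L,
                         min_shift = 20, alpha_percentile = 95, seed = 1L,
                         rectify = TRUE, transient_sd = 2,
                         active_frac = 0.2, min_dwell = 0.5,
                         min_active_bins = 3L) {
  stopifnot(inherits(track, "position_track"))
  n_shuffles <- check_count(n_shuffles, "n_shuffles")
  duration <- nrow(track$samples) / track$rate
  if (duration <= 2 * min_shift)
    stop_invalid("session shorter than twice `min_shift`")

  a <- align_activity(activity, rate, t0, track)
  a <- prep_activity(a, rectify, transient_sd)
  m <- length(a)
  nb <- nrow(occ$dwell)
  flat <- occ$bin_index[, 1] + nb * (occ$bin_index[, 2] - 1L)
  dwell_flat <- as.numeric(occ$dwell)

  # per-bin sums under a circular shift, via samples pre-sorted by bin:
  # one gather + one cumsum per shuffle
  perm <- order(flat)
  counts <- tabulate(flat, nb * nb)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  sum_by_bin_shifted <- function(s) {
    idx <- ((perm - 1L + s) %% m) + 1L
    cs <- c(0, cumsum(a[idx]))
    cs[ends + 1L] - cs[starts]
  }

  obs_map <- compute_rate_map(activity, track, occ, rate, t0, rectify,
                              transient_sd, active_frac = active_frac,
                              min_dwell = min_dwell)
  eligible <- obs_map$active_bins >= min_active_bins
  si_obs <- si_from_sums(sum_by_bin_shifted(0L), dwell_flat, occ$total_time,
                         min_dwell)

  shifts <- with_seed(seed, {
    round(stats::runif(n_shuffles, min_shift, duration - min_shift) *
            track$rate)
  })
  null <- vapply(shifts, function(s)
    si_from_sums(sum_by_bin_shifted(s), dwell_flat, occ$total_time,
                 min_dwell),
    numeric(1))

  pct <- 100 * mean(null < si_obs, na.rm = TRUE)
  crit <- stats::quantile(null, alpha_percentile / 100, type = 7,
                          names = FALSE, na.rm = TRUE)
  structure(list(si = si_obs, shuffle_distribution = null,
                 percentile = pct,
                 is_spatial = isTRUE(eligible && !is.na(si_obs) &&
                                       si_obs > crit),
                 eligible = eligible, active_bins = obs_map$active_bins,
                 n_shuffles = n_shuffles),
            class = "spatial_info_result")
}

#' @export
print.spatial_info_result <- function(x, ...) {
  cat(sprintf(
    "<spatial_info_result> SI %.4f bits (pct %.1f), %d active bins, %s\n",
    x$si, x$percentile, x$active_bins,
    if (x$is_spatial) "spatial" else "not spatial"))
  invisible(x)
}

#' Place-field center of mass
#'
#' Rate-weighted mean of bin-center coordinates over the field: the bins
#' whose rate is at least `field_threshold` times the peak rate.
#'
#' @param map A [compute_rate_map()] result.
#' @param field_threshold Fraction of the peak rate defining the field
#'   (default 0.2).
#' @return List with `x_com`, `y_com` (cm) and `n_field_bins`.
#' @export
field_com <- function(map, field_threshold = 0.2) {
  stopifnot(inherits(map, "rate_map"))
  lam <- map$rate
  peak <- suppressWarnings(max(lam, na.rm = TRUE))
  if (!is.finite(peak) || peak <= 0)
    stop_empty("rate map has no positive activity")
  sel <- which(!is.na(lam) & lam >= field_threshold * peak, arr.ind = TRUE)
  w <- lam[sel]
  cx <- (sel[, 1] - 0.5) * map$bin_size
  cy <- (sel[, 2] - 0.5) * map$bin_size
  list(x_com = sum(w * cx) / sum(w), y_com = sum(w * cy) / sum(w),
       n_field_bins = nrow(sel))
}

# separable Gaussian smoothing of a matrix (zero-padded, sigma in bins,
# kernel truncated at 3 sigma)
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad <- function(v) c(numeric(half), v, numeric(half))
  sm1 <- function(v) as.numeric(stats::filter(pad(v), k, sides = 2))[
    (half + 1):(half + length(v))]
  m <- apply(m, 2, sm1)
  t(apply(m, 1, sm1))
}

# subset a track to the union of [start, end) intervals
subset_track <- function(track, intervals) {
  tt <- track$samples$t_s
  keep <- rep(FALSE, length(tt))
  if (nrow(intervals))
    for (i in seq_len(nrow(intervals)))
      keep <- keep | (tt >= intervals[i, 1] & tt < intervals[i, 2])
  keep
}

#' Place-field COM shift between lever-switch epochs
#'
#' Splits an FR5-switch session into left-lever-active and
#' right-lever-active periods, builds epoch-restricted rate maps per
#' neuron, and reports the x-dimension center-of-mass difference
#' `delta_x = x_com(right epoch) - x_com(left epoch)`. The analysis is
#' restricted to x because the levers and food port share one wall. A
#' lever with zero active time yields `NA` for that epoch, not an error.
#'
#' @param traces A [trace_matrix()].
#' @param track The session [position_track()].
#' @param log The FR5-switch [event_log()].
#' @param field_threshold Passed to [field_com()].
#' @param rectify,transient_sd,active_frac Passed to [compute_rate_map()];
#'   the transient threshold is estimated once per neuron on the full
#'   session so both epochs share a scale.
#' @param smooth_sigma Rate-map smoothing SD in bins for the epoch maps
#'   (default 1; epoch restriction thins per-bin dwell, making unsmoothed
#'   epoch maps dominated by single-visit spikes).
#' @param min_dwell Minimum epoch-map bin dwell in seconds (default 1).
#' @param activity_mode Activity reduction for the epoch maps; default
#'   `"onsets"` (discrete transient starts), since decay tails carried
#'   along stereotyped lever-to-port runs otherwise drag the
#'   center of mass toward the travel path.
#' @param transient_sd_onset Detection threshold (robust SDs) used when
#'   `activity_mode = "onsets"`; higher than the fluorescence threshold
#'   because an onset detector must keep noise upcrossings negligible.
#' @param min_active_bins Eligibility floor per epoch map (default 3).
#' @return data.frame of class `com_shift`: `neuron_id`, `x_com_left`,
#'   `x_com_right`, `delta_x`, `eligible`; attribute `epoch_occupancy`
#'   (seconds of dwell in each epoch) for QC.
#' @export
switch_com_shift <- function(traces, track, log, field_threshold = 0.2,
                             rectify = TRUE, transient_sd = 2,
                             active_frac = 0.2, min_active_bins = 3L,
                             smooth_sigma = 1, min_dwell = 1,
                             activity_mode = "onsets",
                             transient_sd_onset = 3.5) {
  if (identical(activity_mode, "onsets")) transient_sd <- transient_sd_onset
  stopifnot(inherits(traces, "trace_matrix"),
            inherits(track, "position_track"), inherits(log, "event_log"))
  iv <- lever_intervals(log)
  if (!nrow(iv$left) || !nrow(iv$right))
    stop_invalid("log must contain at least one block per lever")

  # activity is prepared (thresholded / onset-detected) once on the full
  # session; epoch maps then see the prepared values as-is
  epoch_com <- function(keep, prepared) {
    if (!any(keep)) return(list(x = NA_real_, eligible = FALSE))
    sub <- position_track(track$samples$t_s[keep], track$samples$x_cm[keep],
                          track$samples$y_cm[keep], track$rate,
                          track$arena_width, track$arena_height)
    occ <- compute_occupancy(sub)
    mapped <- tryCatch(
      compute_rate_map(prepared[keep], sub, occ, rectify = FALSE,
                       transient_sd = 0,
                       active_frac = active_frac,
                       smooth_sigma = smooth_sigma,
                       min_dwell = min_dwell,
                       pre_aligned = TRUE),
      opercal_empty_result = function(e) NULL)
    if (is.null(mapped)) return(list(x = NA_real_, eligible = FALSE))
    com <- tryCatch(field_com(mapped, field_threshold),
                    opercal_empty_result = function(e) NULL)
    list(x = if (is.null(com)) NA_real_ else com$x_com,
         eligible = mapped$active_bins >= min_active_bins)
  }

  keep_l <- subset_track(track, iv$left)
  keep_r <- subset_track(track, iv$right)
  n <- nrow(traces$values)
  xl <- xr <- numeric(n); elig <- logical(n)
  for (j in seq_len(n)) {
    a <- align_activity(traces$values[j, ], traces$rate, traces$t0, track)
    ap <- prep_activity(a, rectify, transient_sd, stats::mad(a),
                        activity_mode)
    L <- epoch_com(keep_l, ap); R <- epoch_com(keep_r, ap)
    xl[j] <- L$x; xr[j] <- R$x
    elig[j] <- L$eligible && R$eligible
  }
  out <- data.frame(neuron_id = traces$neuron_ids, x_com_left = xl,
                    x_com_right = xr, delta_x = xr - xl, eligible = elig,
                    stringsAsFactors = FALSE)
  attr(out, "epoch_occupancy") <- c(left = sum(keep_l) / track$rate,
                                    right = sum(keep_r) / track$rate)
  class(out) <- c("com_shift", "data.frame")
  out
}

#' Write a spatial-results table as CSV
#'
#' Columns `neuron_id,si_bits,percentile,active_bins,eligible,is_spatial`
#' plus, when a [switch_com_shift()] result is supplied, `x_com_left`,
#' `x_com_right`, `delta_x`.
#'
#' @param results Named list of [shuffle_test()] results (names = neuron
#'   ids).
#' @param path CSV file path.
#' @param com_shift Optional [switch_com_shift()] data.frame to merge.
#' @return `path`, invisibly.
#' @export
write_spatial_csv <- function(results, path, com_shift = NULL) {
  df <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(neuron_id = id, si_bits = r$si, percentile = r$percentile,
               active_bins = r$active_bins, eligible = r$eligible,
               is_spatial = r$is_spatial, stringsAsFactors = FALSE)
  }))
  if (!is.null(com_shift))
    df <- merge(df, com_shift[, c("neuron_id", "x_com_left", "x_com_right",
                                  "delta_x")], by = "neuron_id",
                all.x = TRUE, sort = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a 15 x 15 map as CSV
#'
#' @param map A [compute_rate_map()] or [compute_occupancy()] result.
#' @param path CSV file path.
#' @return `path`, invisibly. Rows are y bins (top row = highest y),
#'   columns x bins.
#' @export
write_map_csv <- function(map, path) {
  m <- if (inherits(map, "rate_map")) map$rate else map$dwell
  # transpose so the file reads like the arena seen from above
  utils::write.table(t(m)[rev(seq_len(ncol(m))), ], path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
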