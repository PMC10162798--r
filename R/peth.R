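#' Build a peri-event time histogram (PETH)
#'
#' Bins one neuron's trace around each event into 100 ms bins over a
#' -3..+3 s window (60 bins per trial). Bins are half-open
#' `[start, end)` in event-relative time; a bin's value is the mean of the
#' trace samples falling in it. Events whose window is not fully covered by
#' the trace are dropped (their count is recorded in `n_dropped`).
#'
#' @param trace Numeric vector: one neuron's activity samples.
#' @param rate Sampling rate of `trace`, Hz. Must give at least one sample
#'   per bin (`rate * bin_width >= 1`).
#' @param event_times Event times, seconds.
#' @param window Event-relative analysis window, seconds (default -3..3).
#' @param bin_width Bin width in seconds (default 0.1).
#' @param baseline_window Baseline period within `window` (default -3..-1).
#' @param event_window Period scanned for modulation (default -0.5..0.5).
#' @param t0 Time of the first trace sample, seconds.
#' @param event_kind,neuron_id Identifiers carried into results.
#' @return An object of class `peth`: list with `matrix` (trials x bins),
#'   `bin_edges`, `bin_width`, `window`, `baseline_window`, `event_window`,
#'   `event_kind`, `neuron_id`, `n_dropped`.
#' @export
build_peth <- function(trace, rate, event_times, window = c(-3, 3),
                       bin_width = 0.1, baseline_window = c(-3, -1),
                       event_window = c(-0.5, 0.5), t0 = 0,
                       event_kind = "event", neuron_id = "n001") {
  check_positive_scalar(rate, "rate")
  check_positive_scalar(bin_width, "bin_width")
  if (length(window) != 2 || diff(window) <= 0)
    stop_invalid("`window` must be an increasing pair")
  if (baseline_window[1] < window[1] || baseline_window[2] > window[2] ||
      event_window[1] < window[1] || event_window[2] > window[2])
    stop_invalid("baseline and event windows must lie inside `window`")
  if (rate * bin_width < 1 - 1e-9)
    stop_invalid("`rate` too low: need at least one sample per bin")
  n_bins <- round(diff(window) / bin_width)
  if (abs(n_bins * bin_width - diff(window)) > 1e-9)
    stop_invalid("`bin_width` must tile `window` exactly")
  if (!length(event_times)) stop_empty("no events supplied")

  n <- length(trace)
  t_first <- t0; t_last <- t0 + (n - 1L) / rate
  eps <- 1e-9
  # full coverage: every bin, including the last half-open one, must contain
  # at least one sample
  usable <- event_times + window[1] >= t_first - eps &
    event_times + window[2] - bin_width <= t_last + eps
  dropped <- sum(!usable)
  ev <- event_times[usable]
  if (!length(ev))
    stop_empty("no events with full window coverage")

  times <- t0 + (seq_len(n) - 1L) / rate
  m <- matrix(NA_real_, length(ev), n_bins)
  for (i in seq_along(ev)) {
    rel <- times - ev[i]
    sel <- rel >= window[1] - eps & rel < window[2] - eps
    idx <- floor((rel[sel] - window[1]) / bin_width + eps) + 1L
    idx[idx > n_bins] <- n_bins
    sums <- tabulate(idx, n_bins)
    m[i, ] <- as.numeric(rowsum(trace[sel], idx)) / sums
  }
  structure(list(matrix = m,
                 bin_edges = window[1] + bin_width * (0:n_bins),
                 bin_width = bin_width, window = window,
                 baseline_window = baseline_window,
                 event_window = event_window,
                 event_kind = event_kind, neuron_id = neuron_id,
                 n_dropped = dropped),
            class = "peth")
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf(
    "<peth> %s / %s: %d trials x %d bins (%.0f ms), %d dropped event(s)\n",
    x$neuron_id, x$event_kind, nrow(x$matrix), ncol(x$matrix),
    1000 * x$bin_width, x$n_dropped))
  invisible(x)
}

# column indices of bins lying wholly inside `win`
bins_in_window <- function(peth, win) {
  lo <- peth$bin_edges[-length(peth$bin_edges)]
  hi <- peth$bin_edges[-1]
  which(lo >= win[1] - 1e-9 & hi <= win[2] + 1e-9)
}

#' Select isolated events for clean baseline alignment
#'
#' Keeps only events preceded by at least `min_gap` seconds without
#' another event of the same kind. Aligning to isolated events keeps the
#' PETH baseline window free of the preceding event's calcium decay tail
#' (the indicator outlasts the behavior by a couple of seconds), the same
#' rationale as aligning to the first press of a ratio run.
#'
#' @param times Sorted event times in seconds.
#' @param min_gap Minimum silence before an event, seconds. The default
#'   covers the 3 s pre-event window plus a 2.5 s indicator tail.
#' @return The subset of `times` that is isolated.
#' @export
isolated_events <- function(times, min_gap = 5.5) {
  if (!length(times)) return(times)
  times <- sort(times)
  keep <- c(TRUE, diff(times) >= min_gap)
  times[keep]
}

#' Baseline threshold of a PETH
#'
#' The empirical 99th percentile (linear interpolation between order
#' statistics, `stats::quantile` type 7) of the baseline-period bin values.
#' By default values are pooled across trials (trials x 20 values for the
#' standard windows); `baseline = "averaged"` instead takes the percentile
#' of the trial-averaged baseline bins.
#'
#' @param peth A [build_peth()] result.
#' @param prob Percentile level (default 0.99).
#' @param baseline `"pooled"` or `"averaged"`.
#' @return Threshold in activity units.
#' @export
baseline_threshold <- function(peth, prob = 0.99,
                               baseline = c("pooled", "averaged")) {
  stopifnot(inherits(peth, "peth"))
  baseline <- match.arg(baseline)
  cols <- bins_in_window(peth, peth$baseline_window)
  vals <- if (baseline == "pooled") as.numeric(peth$matrix[, cols])
  else colMeans(peth$matrix[, cols, drop = FALSE])
  unname(stats::quantile(vals, prob, type = 7, names = FALSE))
}

#' Classify a neuron as significantly event-modulated
#'
#' Implements the baseline-percentile, consecutive-bin criterion: the
#' trial-averaged PETH must exceed the 99th percentile of baseline activity
#' for at least three consecutive 100 ms bins within the event window
#' (-0.5..+0.5 s). Only increases are detected.
#'
#' @param peth A [build_peth()] result.
#' @param prob Baseline percentile level (default 0.99).
#' @param n_consec Required run of supra-threshold bins (default 3).
#' @param scan `"event"` restricts the run search to the event window;
#'   `"full"` scans the whole PETH window.
#' @param baseline Passed to [baseline_threshold()].
#' @return An object of class `modulation_result`: list with `neuron_id`,
#'   `event_kind`, `is_modulated`, `threshold`, `run_length` (longest
#'   supra-threshold run in the scanned window), `run_start_bin` (1-based
#'   index into the 60-bin trace, `NA` if no run), `n_trials`,
#'   `mean_trace`, `z_trace` (baseline mean/SD normalized).
#' @export
classify_modulated <- function(peth, prob = 0.99, n_consec = 3L,
                               scan = c("event", "full"),
                               baseline = c("pooled", "averaged")) {
  stopifnot(inherits(peth, "peth"))
  scan <- match.arg(scan)
  n_consec <- check_count(n_consec, "n_consec")
  thr <- baseline_threshold(peth, prob, baseline)
  mean_trace <- colMeans(peth$matrix)

  cols <- if (scan == "event") bins_in_window(peth, peth$event_window)
  else seq_along(mean_trace)
  above <- mean_trace[cols] > thr
  run_length <- 0L; run_start <- NA_integer_
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- which(r$values)[which.max(r$lengths[r$values])]
    run_length <- r$lengths[best]
    run_start <- cols[starts[best]]
  }
  bl_cols <- bins_in_window(peth, peth$baseline_window)
  bl_mu <- mean(mean_trace[bl_cols]); bl_sd <- stats::sd(mean_trace[bl_cols])
  structure(list(neuron_id = peth$neuron_id, event_kind = peth$event_kind,
                 is_modulated = run_length >= n_consec, threshold = thr,
                 run_length = run_length, run_start_bin = run_start,
                 n_trials = nrow(peth$matrix),
                 mean_trace = mean_trace,
                 z_trace = if (bl_sd > 0) (mean_trace - bl_mu) / bl_sd
                 else mean_trace * NA_real_),
            class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation_result> %s / %s: %smodulated (run %d, thr %.3g)\n",
              x$neuron_id, x$event_kind, if (x$is_modulated) "" else "not ",
              x$run_length, x$threshold))
  invisible(x)
}

#' Attribute lever modulation with the either-lever exclusion rule
#'
#' Neurons significantly modulated by both levers are categorized `both`
#' and excluded from the single-lever categories; `left_only`/`right_only`
#' require exactly one significant lever. Reward and extension modulation
#' are carried as independent flags (a neuron sits in exactly one lever
#' category but may carry several event flags).
#'
#' @param left,right,reward,extension [classify_modulated()] results for
#'   the same neuron (reward/extension may be `NULL` when not tested).
#' @return An object of class `lever_attribution`: list with `neuron_id`,
#'   `category` (one of both/left_only/right_only/reward/extension/
#'   unmodulated), and logical `flags` per event kind.
#' @export
attribute_lever_modulation <- function(left, right, reward = NULL,
                                       extension = NULL) {
  res <- list(left = left, right = right, reward = reward,
              extension = extension)
  res <- res[!vapply(res, is.null, logical(1))]
  ids <- unique(vapply(res, `[[`, character(1), "neuron_id"))
  if (length(ids) != 1L)
    stop_invalid("modulation results refer to different neurons")
  flags <- vapply(res, `[[`, logical(1), "is_modulated")
  l <- isTRUE(flags[["left"]]); r <- isTRUE(flags[["right"]])
  category <- if (l && r) "both"
  else if (l) "left_only"
  else if (r) "right_only"
  else if (isTRUE(flags[["reward"]])) "reward"
  else if (isTRUE(flags[["extension"]])) "extension"
  else "unmodulated"
  structure(list(neuron_id = ids, category = category, flags = flags),
            class = "lever_attribution")
}

#' Percent of the population modulated, by event kind
#'
#' @param results List of [classify_modulated()] results (possibly several
#'   event kinds).
#' @param total Population size the percentages refer to.
#' @return data.frame `event_kind`, `n_modulated`, `total`, `percent`.
#' @export
percent_modulated <- function(results, total) {
  total <- check_count(total, "total")
  kinds <- vapply(results, `[[`, character(1), "event_kind")
  mod <- vapply(results, `[[`, logical(1), "is_modulated")
  out <- do.call(rbind, lapply(unique(kinds), function(k) {
    n <- sum(mod[kinds == k])
    if (n > total) stop_invalid("modulated count exceeds population size")
    data.frame(event_kind = k, n_modulated = n, total = total,
               percent = 100 * n / total, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(event_kind = character(0), n_modulated = integer(0),
                      total = integer(0), percent = numeric(0))
  out
}

#' Write modulation results as CSV
#'
#' Columns `neuron_id,event_kind,is_modulated,threshold,run_length,
#' run_start_bin`.
#'
#' @param results List of [classify_modulated()] results.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_modulation_csv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(neuron_id = r$neuron_id, event_kind = r$event_kind,
               is_modulated = r$is_modulated, threshold = r$threshold,
               run_length = r$run_length, run_start_bin = r$run_start_bin,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
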