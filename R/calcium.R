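#' Tuning kinds for synthetic neurons
#'
#' Event-locked kinds respond to a behavioral event; `place` carries a fixed
#' (allocentric) Gaussian place field; `active_lever` carries a field that
#' follows whichever lever is currently extended (the lever-locked
#' population the switch-task analysis is designed to detect); `none` is
#' untuned (baseline transients only).
#'
#' @return Character vector of recognized tuning kinds.
#' @export
tuning_kinds <- function() {
  c("press_left", "press_right", "press_both", "reward", "extension",
    "place", "active_lever", "none")
}

#' Generate a ground-truth-labeled synthetic population
#'
#' Draws per-neuron tuning labels from a seeded multinomial over
#' `kind_fractions` and attaches response parameters. Place-field centers
#' are uniform over the arena.
#'
#' @param n_neurons Population size.
#' @param kind_fractions Named numeric vector/list of label probabilities
#'   over [tuning_kinds()]; must be nonnegative and sum to 1 (tol 1e-9).
#' @param amplitude Transient peak amplitude, in multiples of the trace
#'   noise SD.
#' @param place_params List with `width` (isotropic Gaussian SD, cm) for
#'   place / active-lever fields.
#' @param baseline_rate Baseline transient rate, events/s.
#' @param response_latency Event-to-response-onset latency, seconds.
#' @param response_duration Duration of the evoked calcium drive, seconds;
#'   evoked responses are bursts sustained this long (peak still
#'   `amplitude`), a single-sample duration giving a bare transient.
#' @param seed Integer seed.
#' @param arena_width,arena_height Arena size in cm for place centers.
#' @return A data.frame of class `ground_truth`, one row per neuron:
#'   `neuron_id`, `tuning_kind`, `response_amplitude`, `response_latency`,
#'   `response_duration`, `place_x`, `place_y`, `place_width`,
#'   `baseline_rate`.
#' @export
generate_population <- function(n_neurons, kind_fractions, amplitude = 3,
                                place_params = list(width = 4),
                                baseline_rate = 0.02,
                                response_latency = 0.05,
                                response_duration = 0.25,
                                seed = 1L, arena_width = 30,
                                arena_height = 30) {
  n_neurons <- check_count(n_neurons, "n_neurons")
  fr <- unlist(kind_fractions)
  if (is.null(names(fr)) || !all(names(fr) %in% tuning_kinds()))
    stop_invalid("`kind_fractions` must be named with recognized tuning kinds")
  if (any(fr < 0)) stop_invalid("`kind_fractions` must be nonnegative")
  if (abs(sum(fr) - 1) > 1e-9)
    stop_invalid(sprintf("`kind_fractions` must sum to 1 (got %.12f)", sum(fr)))
  if (amplitude < 0) stop_invalid("`amplitude` must be >= 0")

  truth <- with_seed(seed, {
    kinds <- sample(names(fr), n_neurons, replace = TRUE, prob = fr)
    has_field <- kinds %in% c("place", "active_lever")
    px <- ifelse(kinds == "place", stats::runif(n_neurons, 0, arena_width),
                 NA_real_)
    py <- ifelse(kinds == "place", stats::runif(n_neurons, 0, arena_height),
                 NA_real_)
    data.frame(
      neuron_id = sprintf("n%03d", seq_len(n_neurons)),
      tuning_kind = kinds,
      response_amplitude = rep(amplitude, n_neurons),
      response_latency = rep(response_latency, n_neurons),
      response_duration = rep(response_duration, n_neurons),
      place_x = px, place_y = py,
      place_width = ifelse(has_field, place_params$width, NA_real_),
      baseline_rate = rep(baseline_rate, n_neurons),
      stringsAsFactors = FALSE)
  })
  structure(truth, class = c("ground_truth", "data.frame"),
            arena = c(width = arena_width, height = arena_height),
            seed = seed)
}

#' Write / read ground truth as JSON
#' @param truth A [generate_population()] result.
#' @param path JSON file path.
#' @return `write_ground_truth` returns `path` invisibly; the reader
#'   returns the reconstructed `ground_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(arena = as.list(attr(truth, "arena")), seed = attr(truth, "seed"),
         neurons = as.data.frame(truth)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj$neurons, class = c("ground_truth", "data.frame"),
            arena = unlist(obj$arena), seed = obj$seed)
}

#' Sampled calcium transient kernel
#'
#' Double-exponential surrogate for a fast GCaMP indicator response:
#' `k(t) = exp(-t/decay_tau) - exp(-t/rise_tau)`, normalized to unit peak
#' and truncated at `5 * decay_tau`. `k(0) = 0`; the analytic peak is at
#' `t* = (log(decay_tau) - log(rise_tau)) / (1/rise_tau - 1/decay_tau)`.
#'
#' @param rise_tau Rise time constant, seconds (must be < `decay_tau`).
#' @param decay_tau Decay time constant, seconds.
#' @param rate Sampling rate, Hz.
#' @return Numeric vector of class `transient_kernel` (attributes
#'   `rise_tau`, `decay_tau`, `rate`), first sample at t = 0.
#' @export
transient_kernel <- function(rise_tau = 0.05, decay_tau = 0.5, rate = 30) {
  check_positive_scalar(rise_tau, "rise_tau")
  check_positive_scalar(decay_tau, "decay_tau")
  check_positive_scalar(rate, "rate")
  if (rise_tau >= decay_tau)
    stop_invalid("`rise_tau` must be strictly less than `decay_tau`")
  t <- seq(0, 5 * decay_tau, by = 1 / rate)
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k <- k / max(k)
  structure(k, class = "transient_kernel", rise_tau = rise_tau,
            decay_tau = decay_tau, rate = rate, times = t)
}

#' Analytic peak time of a transient kernel
#' @param kernel A [transient_kernel()].
#' @return Peak time in seconds.
#' @export
kernel_peak_time <- function(kernel) {
  r <- attr(kernel, "rise_tau"); d <- attr(kernel, "decay_tau")
  (log(d) - log(r)) / (1 / r - 1 / d)
}

#' Construct a trace matrix
#'
#' The container for extracted per-neuron activity traces consumed by the
#' analysis: neurons x samples at a fixed rate.
#'
#' @param values Numeric matrix, one row per neuron.
#' @param rate Sampling rate, Hz.
#' @param t0 Time of the first sample, seconds.
#' @param neuron_ids Row identifiers.
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, rate, t0 = 0,
                         neuron_ids = sprintf("n%03d", seq_len(nrow(values)))) {
  check_positive_scalar(rate, "rate")
  values <- as.matrix(values)
  if (anyNA(values)) stop_invalid("trace matrix contains missing samples")
  if (length(neuron_ids) != nrow(values))
    stop_invalid("`neuron_ids` length must match rows of `values`")
  rownames(values) <- neuron_ids
  structure(list(values = values, rate = rate, t0 = t0,
                 neuron_ids = neuron_ids),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix> %d neurons x %d samples @ %g Hz (t0 = %g s)\n",
              nrow(x$values), ncol(x$values), x$rate, x$t0))
  invisible(x)
}

#' Sample times of a trace matrix
#' @param traces A [trace_matrix()].
#' @return Numeric vector of per-sample times in seconds.
#' @export
trace_times <- function(traces) {
  traces$t0 + (seq_len(ncol(traces$values)) - 1L) / traces$rate
}

# unit evoked response: kernel driven for `dur` seconds, peak normalized
# to 1. Evoked calcium responses are multi-spike bursts, so the drive is a
# box of length `dur` rather than a single impulse; dur <= one sample
# reduces to the bare kernel.
evoked_response <- function(kernel, dur, rate) {
  nd <- max(1L, round(dur * rate))
  u <- stats::convolve(c(rep(1, nd), numeric(length(kernel))), rev(kernel),
                       type = "open")[seq_len(nd + length(kernel))]
  list(drive_len = nd, scale = 1 / max(u))
}

# events (times) a neuron of the given tuning kind responds to
matching_event_times <- function(kind, log) {
  switch(kind,
         press_left = event_times(log, "press_left"),
         press_right = event_times(log, "press_right"),
         press_both = event_times(log, "press_any"),
         reward = event_times(log, "reward"),
         extension = event_times(log, "extension_any"),
         numeric(0))
}

#' Synthesize calcium traces for a labeled population
#'
#' Each neuron's trace is a sum of unit-kernel transients plus i.i.d.
#' Gaussian noise. Untuned and event-locked neurons fire baseline
#' transients as a homogeneous Poisson process at `baseline_rate`;
#' event-locked neurons add one evoked response per matching event: the
#' kernel driven for `response_duration` seconds starting at
#' `event time + response_latency`, peak scaled to the neuron's amplitude
#' (a sustained burst, as press-locked calcium responses are).
#' Place and active-lever neurons fire an
#' inhomogeneous Poisson process whose rate is
#' `baseline_rate * (1 + (gain - 1) * exp(-d^2 / (2 w^2)))`, `d` being the
#' animal's distance to the (fixed or currently-extended-lever) field
#' center; the rate drops to `baseline_rate` when no lever is out for
#' active-lever cells. All transient peaks are
#' `response_amplitude * noise SD` fluorescence units (when `noise_sd = 0`
#' the unit is 1, so noise-free constructions keep their signal).
#'
#' @param truth A [generate_population()] result.
#' @param log The session [event_log()].
#' @param track The session [position_track()]; may be `NULL` when the
#'   population contains no place or active-lever neurons.
#' @param rate Trace sampling rate, Hz.
#' @param kernel A [transient_kernel()] sampled at `rate`.
#' @param noise_sd Gaussian noise SD in fluorescence units.
#' @param seed Integer seed.
#' @param gain Peak-over-baseline transient-rate gain inside a field.
#' @param spont_amp_frac Peak amplitude of spontaneous baseline transients,
#'   as a fraction of the neuron's evoked amplitude (default 0.5:
#'   spontaneous single-event transients are smaller than evoked bursts).
#'   Field-driven transients of place/active-lever neurons are their
#'   signal and keep the full amplitude.
#' @param drift_ar1 Optional AR(1) coefficient adding slow drift (0 = off).
#' @param drift_sd Innovation SD of the drift process.
#' @return A [trace_matrix()] with attribute `signal` (the noise-free
#'   signal component) and attribute `truth`.
#' @export
synthesize_traces <- function(truth, log, track = NULL, rate = 30,
                              kernel = transient_kernel(rate = rate),
                              noise_sd = 1, seed = 1L, gain = 8,
                              spont_amp_frac = 0.5,
                              drift_ar1 = 0, drift_sd = 0) {
  stopifnot(inherits(truth, "ground_truth"), inherits(log, "event_log"))
  check_positive_scalar(rate, "rate")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  needs_track <- any(truth$tuning_kind %in% c("place", "active_lever"))
  if (needs_track && is.null(track))
    stop_invalid("population contains place/active_lever neurons but no track")
  if (!is.null(track)) {
    tt <- track$samples$t_s
    if (tt[1] > 1e-9 || tt[length(tt)] < log$duration - 1.5 / track$rate)
      stop_invalid("track does not cover the session interval of the log")
  }

  n <- floor(log$duration * rate) + 1L
  t <- (seq_len(n) - 1L) / rate
  dt <- 1 / rate
  amp_unit <- if (noise_sd > 0) noise_sd else 1
  geom <- arena_geometry()

  # per-sample field-center distance helpers
  if (!is.null(track)) {
    ti <- pmin(pmax(round((t - track$samples$t_s[1]) * track$rate) + 1L, 1L),
               nrow(track$samples))
    ax <- track$samples$x_cm[ti]; ay <- track$samples$y_cm[ti]
    iv <- lever_intervals(log)
    lever_x <- rep(NA_real_, n); lever_y <- rep(NA_real_, n)
    mark <- function(m, px, py) {
      if (nrow(m)) for (i in seq_len(nrow(m))) {
        sel <- t >= m[i, 1] & t < m[i, 2]
        lever_x[sel] <<- px; lever_y[sel] <<- py
      }
    }
    mark(iv$left, geom$lever_left["x"], geom$lever_left["y"])
    mark(iv$right, geom$lever_right["x"], geom$lever_right["y"])
  }

  nk <- length(kernel)
  vals <- matrix(0, nrow(truth), n)
  signal <- matrix(0, nrow(truth), n)
  with_seed(seed, {
    for (j in seq_len(nrow(truth))) {
      kind <- truth$tuning_kind[j]
      amp <- truth$response_amplitude[j] * amp_unit
      imp <- numeric(n)
      # baseline / place-modulated Poisson transients
      rate_t <- rep(truth$baseline_rate[j], n)
      if (kind == "place") {
        d2 <- (ax - truth$place_x[j])^2 + (ay - truth$place_y[j])^2
        rate_t <- rate_t * (1 + (gain - 1) *
                              exp(-d2 / (2 * truth$place_width[j]^2)))
      } else if (kind == "active_lever") {
        d2 <- (ax - lever_x)^2 + (ay - lever_y)^2
        g <- ifelse(is.na(lever_x), 0,
                    exp(-d2 / (2 * truth$place_width[j]^2)))
        rate_t <- rate_t * (1 + (gain - 1) * g)
      }
      spont_amp <- if (kind %in% c("place", "active_lever")) amp
      else amp * spont_amp_frac
      fires <- stats::runif(n) < rate_t * dt
      imp[fires] <- imp[fires] + spont_amp
      # event-locked responses: kernel driven for response_duration seconds
      # from event + latency, peak scaled to `amp`
      ev <- matching_event_times(kind, log) + truth$response_latency[j]
      if (length(ev)) {
        er <- evoked_response(kernel, truth$response_duration[j], rate)
        idx <- round(ev * rate) + 1L
        idx <- idx[idx >= 1L & idx <= n]
        for (i in idx) {
          i1 <- min(n, i + er$drive_len - 1L)
          imp[i:i1] <- imp[i:i1] + amp * er$scale
        }
      }
      sig <- stats::convolve(imp, rev(kernel), type = "open")[seq_len(n)]
      if (drift_ar1 > 0 && drift_sd > 0) {
        dr <- stats::filter(stats::rnorm(n, 0, drift_sd), drift_ar1,
                            method = "recursive")
        sig <- sig + as.numeric(dr)
      }
      signal[j, ] <- sig
      vals[j, ] <- sig + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    }
  })
  out <- trace_matrix(vals, rate, t0 = 0, neuron_ids = truth$neuron_id)
  attr(out, "signal") <- signal
  attr(out, "truth") <- truth
  out
}

#' Write / read a trace matrix as CSV
#'
#' One row per neuron, first column `neuron_id`; rate and t0 in
#' `<path>.json`. Intended for small fixtures.
#'
#' @param traces A [trace_matrix()].
#' @param path CSV file path.
#' @return `write_traces_csv` returns `path` invisibly; the reader returns
#'   the reconstructed `trace_matrix`.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_matrix"))
  df <- data.frame(neuron_id = traces$neuron_ids, traces$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(rate = traces$rate, t0 = traces$t0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trace_matrix(as.matrix(df[, -1, drop = FALSE]), meta$rate, meta$t0,
               neuron_ids = df$neuron_id)
}
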