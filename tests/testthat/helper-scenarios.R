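# Shared scenario builders and independent oracles used across test files.

# Two-lever delay session with a press-tuned subpopulation: the standard
# event-recovery scenario (trials are >= 3 s apart by task design, so the
# PETH baseline window is free of same-kind events).
delay_recovery_scenario <- function(seed, n_neurons = 200,
                                    press_frac = 0.3, amplitude = 3,
                                    duration = 600) {
  log <- simulate_two_lever_delay_session(
    duration, presser_policy(6, 0, "poisson"), seed = seed)
  truth <- generate_population(
    n_neurons, c(press_both = press_frac, none = 1 - press_frac),
    amplitude = amplitude, seed = seed + 10L)
  traces <- synthesize_traces(truth, log, NULL, seed = seed + 20L)
  list(log = log, truth = truth, traces = traces,
       press_times = isolated_events(event_times(log, "press_any")))
}

# FR5 lever-switch scenario with lever-locked and port-anchored allocentric
# populations (high-SNR settings: tight fields, strong transients).
switch_scenario <- function(seed, n_neurons = 40) {
  log <- simulate_fr5_switch_session(
    600, presser_policy(12, 2, "poisson"), seed = seed)
  track <- simulate_position_track(log, rate = 30, seed = seed + 1L,
                                   bias = 3, port_dwell = 5)
  truth <- generate_population(
    n_neurons, c(active_lever = 0.5, place = 0.5),
    baseline_rate = 0.5, amplitude = 6,
    place_params = list(width = 2), seed = seed + 2L)
  port <- arena_geometry()$food_port
  truth$place_x[truth$tuning_kind == "place"] <- port["x"]
  truth$place_y[truth$tuning_kind == "place"] <- port["y"]
  traces <- synthesize_traces(truth, log, track, seed = seed + 3L)
  list(log = log, track = track, truth = truth, traces = traces)
}

# Independent brute-force reimplementation of the modulation criterion:
# direct percentile + exhaustive scan over every n_consec-bin run.
brute_classify <- function(peth, prob = 0.99, n_consec = 3L) {
  edges <- peth$bin_edges
  lo <- edges[-length(edges)]; hi <- edges[-1]
  bl <- which(lo >= peth$baseline_window[1] - 1e-9 &
                hi <= peth$baseline_window[2] + 1e-9)
  ew <- which(lo >= peth$event_window[1] - 1e-9 &
                hi <= peth$event_window[2] + 1e-9)
  thr <- as.numeric(stats::quantile(as.numeric(peth$matrix[, bl]), prob,
                                    type = 7))
  mt <- colMeans(peth$matrix)
  hit <- FALSE
  for (s in seq_along(ew)) {
    e <- s + n_consec - 1L
    if (e > length(ew)) break
    ok <- TRUE
    for (k in s:e) if (!(mt[ew[k]] > thr)) { ok <- FALSE; break }
    if (ok) { hit <- TRUE; break }
  }
  list(is_modulated = hit, threshold = thr)
}

# Hand-built PETH object (trials x 60 bins on the standard windows) for
# criterion unit tests.
make_peth <- function(mat, bin_width = 0.1, window = c(-3, 3),
                      baseline_window = c(-3, -1),
                      event_window = c(-0.5, 0.5)) {
  n_bins <- round(diff(window) / bin_width)
  stopifnot(ncol(mat) == n_bins)
  structure(list(matrix = mat,
                 bin_edges = window[1] + bin_width * (0:n_bins),
                 bin_width = bin_width, window = window,
                 baseline_window = baseline_window,
                 event_window = event_window,
                 event_kind = "event", neuron_id = "n001", n_dropped = 0L),
            class = "peth")
}

# Random small PETH with an optional injected supra-baseline response.
random_peth <- function(seed, n_trials = 8, inject = FALSE) {
  set.seed(seed)
  mat <- matrix(rnorm(n_trials * 60), n_trials, 60)
  if (inject) {
    resp_cols <- 31:34
    mat[, resp_cols] <- mat[, resp_cols] + 5
  }
  make_peth(mat)
}
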