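#' Default pipeline configuration
#'
#' All analysis parameters default to the task's stated values: -3..+3 s
#' PETH window, 100 ms bins, -3..-1 s baseline, +/-0.5 s event window,
#' 99th-percentile threshold, 3 consecutive bins, 15 x 15 grid of 2 cm
#' bins, eligibility at >= 3 active bins. Simulation defaults are the
#' session conditions (600 s imaging session, 30 Hz traces).
#'
#' @param task Task list: `type` one of `"fr"`, `"fr5_switch"`,
#'   `"two_lever_delay"`, `"noncontingent"`; optional `ratio`, `duration`.
#' @param population Population list passed to [generate_population()]:
#'   `n_neurons`, `kind_fractions`, `amplitude`, ...
#' @param seed Master seed; sub-seeds for the policy, track, and traces are
#'   derived from it.
#' @param ... Overrides for analysis parameters (`bin_width`, `window`,
#'   `baseline_window`, `event_window`, `percentile`, `n_consec`,
#'   `n_shuffles`, `min_shift`, `alpha_percentile`, `rate`, `run_spatial`,
#'   `isolation_gap` - minimum silence before an aligned event, see
#'   [isolated_events()]; 0 aligns to every event).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(task = list(type = "fr", ratio = 5,
                                        duration = 600),
                            population = list(n_neurons = 50,
                                              kind_fractions = c(press_both = 0.15,
                                                                 reward = 0.05,
                                                                 place = 0.1,
                                                                 none = 0.7)),
                            seed = 1L, ...) {
  cfg <- list(task = task, population = population, seed = seed,
              rate = 30, window = c(-3, 3), bin_width = 0.1,
              baseline_window = c(-3, -1), event_window = c(-0.5, 0.5),
              percentile = 0.99, n_consec = 3L,
              n_bins = 15L, bin_size = 2, n_shuffles = 1000L,
              min_shift = 20, alpha_percentile = 95,
              min_active_bins = 3L, run_spatial = TRUE,
              isolation_gap = 5.5,
              noise_sd = 1, press_rate = 10, post_reward_pause = 2,
              policy_mode = "poisson")
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

simulate_task <- function(cfg) {
  task <- cfg$task
  dur <- if (is.null(task$duration)) 600 else task$duration
  pol <- presser_policy(cfg$press_rate, cfg$post_reward_pause,
                        cfg$policy_mode)
  switch(task$type,
         fr = simulate_fr_session(if (is.null(task$ratio)) 1L else task$ratio,
                                  dur, pol, seed = cfg$seed),
         fr5_switch = simulate_fr5_switch_session(dur, pol, seed = cfg$seed),
         two_lever_delay = simulate_two_lever_delay_session(dur, pol,
                                                            seed = cfg$seed),
         noncontingent = simulate_noncontingent_session(dur, seed = cfg$seed),
         stop_invalid(sprintf("unknown task type `%s`", task$type)))
}

# event kinds worth aligning to, given what the log contains
kinds_to_analyze <- function(log) {
  present <- unique(log$events$kind)
  kinds <- list()
  if ("press_left" %in% present) kinds$press_left <- "press_left"
  if ("press_right" %in% present) kinds$press_right <- "press_right"
  if (any(c("press_left", "press_right") %in% present))
    kinds$press_any <- "press_any"
  if ("reward" %in% present) kinds$reward <- "reward"
  if (any(c("lever_extend_left", "lever_extend_right") %in% present))
    kinds$extension <- "extension_any"
  kinds
}

#' Run the full synthetic-session analysis pipeline
#'
#' Simulates the configured session (events, track, labeled population,
#' traces), classifies every neuron against every event kind the session
#' contains, attributes lever modulation with the either-lever exclusion
#' rule, runs the spatial screen when configured, and assembles a session
#' report. The report is bit-reproducible from the config: the same config
#' and seed give the same report hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, event log, track, traces,
#'   ground truth and result tables are written there.
#' @return A list of class `session_report`: `task_label`, `n_neurons`,
#'   `percent_modulated` (data.frame), `attribution_counts` (named vector),
#'   `spatial` (data.frame or `NULL`), `n_dropped_events`,
#'   `provenance` (config hash, seed, package version), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  pop <- config$population
  if (is.null(pop$n_neurons) || pop$n_neurons == 0) {
    report <- structure(
      list(task_label = config$task$type, n_neurons = 0L,
           percent_modulated = percent_modulated(list(), 1)[0, ],
           attribution_counts = integer(0), spatial = NULL,
           n_dropped_events = 0L,
           provenance = list(config_hash = rlang::hash(unclass(config)),
                             seed = config$seed,
                             package_version =
                               as.character(utils::packageVersion("opercal"))),
           config = config),
      class = "session_report")
    warning("configuration requests zero neurons: empty report")
    return(report)
  }

  log <- simulate_task(config)
  track <- simulate_position_track(log, rate = config$rate,
                                   seed = config$seed + 1L)
  truth <- do.call(generate_population,
                   c(pop, list(seed = config$seed + 2L)))
  traces <- synthesize_traces(truth, log, track, rate = config$rate,
                              noise_sd = config$noise_sd,
                              seed = config$seed + 3L)

  kinds <- kinds_to_analyze(log)
  results <- list()
  dropped <- 0L
  per_neuron <- vector("list", nrow(truth))
  names(per_neuron) <- truth$neuron_id
  for (nm in names(kinds)) {
    ev <- event_times(log, kinds[[nm]])
    if (config$isolation_gap > 0) ev <- isolated_events(ev,
                                                        config$isolation_gap)
    if (!length(ev)) next
    for (j in seq_len(nrow(truth))) {
      p <- tryCatch(
        build_peth(traces$values[j, ], config$rate, ev,
                   window = config$window, bin_width = config$bin_width,
                   baseline_window = config$baseline_window,
                   event_window = config$event_window,
                   event_kind = nm, neuron_id = truth$neuron_id[j]),
        opercal_empty_result = function(e) NULL)
      if (is.null(p)) next
      dropped <- dropped + p$n_dropped
      r <- classify_modulated(p, prob = config$percentile,
                              n_consec = config$n_consec)
      results[[length(results) + 1L]] <- r
      per_neuron[[truth$neuron_id[j]]][[nm]] <- r
    }
  }
  pm <- percent_modulated(results, nrow(truth))

  # lever attribution (only meaningful when both levers were analyzed)
  attribution <- NULL
  if (all(c("press_left", "press_right") %in%
          vapply(results, `[[`, character(1), "event_kind"))) {
    attribution <- lapply(per_neuron, function(rr) {
      if (is.null(rr$press_left) || is.null(rr$press_right)) return(NULL)
      attribute_lever_modulation(rr$press_left, rr$press_right,
                                 rr$reward, rr$extension)
    })
    attribution <- attribution[!vapply(attribution, is.null, logical(1))]
  }
  att_counts <- if (length(attribution)) {
    cats <- vapply(attribution, `[[`, character(1), "category")
    table(factor(cats, levels = c("both", "left_only", "right_only",
                                  "reward", "extension", "unmodulated")))
  } else integer(0)

  spatial_df <- NULL
  if (isTRUE(config$run_spatial)) {
    occ <- compute_occupancy(track, config$n_bins, config$bin_size)
    sres <- lapply(seq_len(nrow(truth)), function(j)
      shuffle_test(traces$values[j, ], track, occ,
                   rate = config$rate, n_shuffles = config$n_shuffles,
                   min_shift = config$min_shift,
                   alpha_percentile = config$alpha_percentile,
                   seed = config$seed + 100L + j,
                   min_active_bins = config$min_active_bins))
    spatial_df <- data.frame(
      neuron_id = truth$neuron_id,
      si_bits = vapply(sres, `[[`, numeric(1), "si"),
      percentile = vapply(sres, `[[`, numeric(1), "percentile"),
      active_bins = vapply(sres, `[[`, numeric(1), "active_bins"),
      eligible = vapply(sres, `[[`, logical(1), "eligible"),
      is_spatial = vapply(sres, `[[`, logical(1), "is_spatial"),
      stringsAsFactors = FALSE)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_event_log(log, file.path(out_dir, "events.csv"))
    write_track(track, file.path(out_dir, "track.csv"))
    write_traces_csv(traces, file.path(out_dir, "traces.csv"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
    write_modulation_csv(results, file.path(out_dir, "modulation.csv"))
    if (!is.null(spatial_df))
      utils::write.csv(spatial_df, file.path(out_dir, "spatial.csv"),
                       row.names = FALSE)
  }

  structure(
    list(task_label = log$task_label, n_neurons = nrow(truth),
         percent_modulated = pm, attribution_counts = att_counts,
         spatial = spatial_df, n_dropped_events = dropped,
         provenance = list(config_hash = rlang::hash(unclass(config)),
                           seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("opercal"))),
         config = config),
    class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s: %d neurons\n", x$task_label,
              x$n_neurons))
  if (nrow(x$percent_modulated)) {
    for (i in seq_len(nrow(x$percent_modulated)))
      cat(sprintf("  %-12s %d/%d modulated (%.1f%%)\n",
                  x$percent_modulated$event_kind[i],
                  x$percent_modulated$n_modulated[i],
                  x$percent_modulated$total[i],
                  x$percent_modulated$percent[i]))
  }
  if (!is.null(x$spatial))
    cat(sprintf("  spatial: %d/%d flagged\n", sum(x$spatial$is_spatial),
                nrow(x$spatial)))
  invisible(x)
}

#' Hash of a session report (reproducibility check)
#' @param report A [run_pipeline()] result.
#' @return Character hash of the report's result tables.
#' @export
report_hash <- function(report) {
  stopifnot(inherits(report, "session_report"))
  rlang::hash(list(report$percent_modulated,
                   as.integer(report$attribution_counts), report$spatial))
}

#' Compare a contingent and a non-contingent session report
#'
#' Side-by-side percentages of modulated neurons per event kind, purely
#' descriptive (no hypothesis test).
#'
#' @param report_fr Report from an operant (lever) session.
#' @param report_nc Report from a non-contingent session with the same
#'   population spec.
#' @return data.frame `event_kind`, `percent_contingent`,
#'   `percent_noncontingent`, `difference`.
#' @export
compare_contingent_noncontingent <- function(report_fr, report_nc) {
  stopifnot(inherits(report_fr, "session_report"),
            inherits(report_nc, "session_report"))
  if (report_fr$n_neurons != report_nc$n_neurons)
    stop_invalid("reports have different population sizes")
  kinds <- union(report_fr$percent_modulated$event_kind,
                 report_nc$percent_modulated$event_kind)
  pick <- function(pm, k) {
    i <- match(k, pm$event_kind)
    ifelse(is.na(i), 0, pm$percent[i])
  }
  data.frame(event_kind = kinds,
             percent_contingent = vapply(kinds, pick,
                                         numeric(1), pm = report_fr$percent_modulated),
             percent_noncontingent = vapply(kinds, pick,
                                            numeric(1), pm = report_nc$percent_modulated),
             row.names = NULL, stringsAsFactors = FALSE) |>
    transform(difference = percent_contingent - percent_noncontingent)
}

#' Retrograde-tracing colocalization fractions
#'
#' Per-row percentage of retrogradely labeled neurons colocalized with the
#' marker (`100 * coloc / retro`), and per-region mean and SEM. Rows with
#' zero retrograde counts are reported as 0% and flagged
#' (`undefined = TRUE`) since the fraction is undefined by convention.
#'
#' @param table data.frame with columns `animal`, `hemisphere`, `region`,
#'   `retro_count`, `coloc_count`.
#' @return List with `per_row` (input plus `percent`, `undefined`) and
#'   `per_region` (data.frame `region`, `n`, `mean_percent`,
#'   `sem_percent`).
#' @export
colocalization_fraction <- function(table) {
  need <- c("animal", "hemisphere", "region", "retro_count", "coloc_count")
  if (!all(need %in% names(table)))
    stop_invalid(sprintf("table must have columns: %s",
                         paste(need, collapse = ", ")))
  if (any(table$retro_count < 0 | table$coloc_count < 0))
    stop_invalid("counts must be nonnegative")
  if (any(table$coloc_count > table$retro_count))
    stop_invalid("coloc_count exceeds retro_count")
  per_row <- table
  per_row$undefined <- per_row$retro_count == 0
  per_row$percent <- ifelse(per_row$undefined, 0,
                            100 * per_row$coloc_count / per_row$retro_count)
  per_region <- do.call(rbind, lapply(split(per_row, per_row$region),
                                      function(d)
    data.frame(region = d$region[1], n = nrow(d),
               mean_percent = mean(d$percent),
               sem_percent = stats::sd(d$percent) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)))
  rownames(per_region) <- NULL
  list(per_row = per_row, per_region = per_region)
}

#' Locus-coeruleus retrograde colocalization counts
#'
#' The packaged cell-count table from the retrograde tracing experiment:
#' per animal and hemisphere, the number of retrogradely labeled neurons in
#' the locus coeruleus (LC) and ventral tegmental area (VTA) and how many
#' colocalized with tyrosine hydroxylase. VTA slices were unavailable for
#' one animal.
#'
#' @return data.frame `animal`, `hemisphere`, `region`, `retro_count`,
#'   `coloc_count`.
#' @export
lc_coloc_table <- function() {
  path <- system.file("extdata", "lc_colocalization.csv",
                      package = "opercal")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
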