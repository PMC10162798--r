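#' Virtual presser policy
#'
#' Governs when the simulated animal presses an available lever.
#' `deterministic` mode emits presses at exactly `60/press_rate` second
#' spacing (counted from lever availability); `poisson` mode draws
#' exponential inter-press intervals with the same mean. After a rewarded
#' press the animal pauses for `post_reward_pause` seconds (retrieving the
#' pellet) before the next interval starts.
#'
#' @param press_rate Presses per minute on an available lever (>= 0).
#' @param post_reward_pause Seconds added after each rewarded press.
#' @param mode `"poisson"` or `"deterministic"`.
#' @return An object of class `presser_policy`.
#' @export
presser_policy <- function(press_rate = 10, post_reward_pause = 2,
                           mode = c("poisson", "deterministic")) {
  mode <- match.arg(mode)
  if (!is.numeric(press_rate) || length(press_rate) != 1L || press_rate < 0)
    stop_invalid("`press_rate` must be a nonnegative scalar")
  if (post_reward_pause < 0)
    stop_invalid("`post_reward_pause` must be nonnegative")
  structure(list(press_rate = press_rate,
                 post_reward_pause = post_reward_pause,
                 mode = mode),
            class = "presser_policy")
}

# Draw one inter-press interval (seconds) under `policy`. Returns Inf when
# the press rate is zero.
next_interval <- function(policy) {
  if (policy$press_rate <= 0) return(Inf)
  spacing <- 60 / policy$press_rate
  if (policy$mode == "deterministic") spacing else stats::rexp(1, 1 / spacing)
}

#' Simulate a fixed-ratio (FR-n) session
#'
#' A single lever extends at t = 0 and stays out for the whole session.
#' Every `ratio`-th press triggers a reward, delivered `dispense_latency`
#' seconds after the press (default 0: immediate).
#'
#' @param ratio Fixed-ratio requirement (presses per reward), >= 1.
#' @param duration Session length in seconds.
#' @param policy A [presser_policy()].
#' @param seed Integer seed for the press-time stream.
#' @param dispense_latency Seconds between the completing press and the
#'   reward event.
#' @param lever `"left"` or `"right"`; which lever is used.
#' @return An [event_log()] with `schedule_ratio = ratio`.
#' @export
simulate_fr_session <- function(ratio, duration, policy = presser_policy(),
                                seed = 1L, dispense_latency = 0,
                                lever = c("left", "right")) {
  ratio <- check_count(ratio, "ratio")
  check_positive_scalar(duration, "duration")
  lever <- match.arg(lever)
  if (dispense_latency < 0) stop_invalid("`dispense_latency` must be >= 0")

  press_kind <- paste0("press_", lever)
  times <- c(0); kinds <- c(paste0("lever_extend_", lever))
  with_seed(seed, {
    t <- 0; n_press <- 0L
    repeat {
      t <- t + next_interval(policy)
      if (!is.finite(t) || t > duration) break
      n_press <- n_press + 1L
      times <- c(times, t); kinds <- c(kinds, press_kind)
      if (n_press %% ratio == 0L) {
        tr <- t + dispense_latency
        if (tr <= duration) {
          times <- c(times, tr); kinds <- c(kinds, "reward")
        }
        t <- t + policy$post_reward_pause
      }
    }
  })
  event_log(times, kinds, duration,
            task_label = sprintf("FR%d", ratio),
            schedule_ratio = ratio, seed = seed)
}

#' Simulate the FR5 lever-switch session
#'
#' One lever is available at a time under an FR5 schedule. After five
#' rewards (25 presses) the active lever retracts and the opposite lever
#' extends, so blocks alternate left, right, left, ... for the whole
#' session. The mechanical exchange takes `switch_latency` seconds: the
#' retraction is logged `switch_latency` s after the fifth reward and the
#' new lever a further `switch_latency` s later.
#'
#' @inheritParams simulate_fr_session
#' @param switch_latency Seconds between the block-ending reward and the
#'   lever retraction (and again between retraction and the new extension).
#' @param rewards_per_block Rewards completing a block (5 in the task).
#' @return An [event_log()] with `schedule_ratio = 5`.
#' @export
simulate_fr5_switch_session <- function(duration, policy = presser_policy(),
                                        seed = 1L, switch_latency = 0.1,
                                        rewards_per_block = 5L,
                                        ratio = 5L) {
  check_positive_scalar(duration, "duration")
  ratio <- check_count(ratio, "ratio")
  rewards_per_block <- check_count(rewards_per_block, "rewards_per_block")

  times <- c(0); kinds <- c("lever_extend_left")
  with_seed(seed, {
    side <- "left"; t <- 0
    block_presses <- 0L; block_rewards <- 0L
    repeat {
      t <- t + next_interval(policy)
      if (!is.finite(t) || t > duration) break
      block_presses <- block_presses + 1L
      times <- c(times, t); kinds <- c(kinds, paste0("press_", side))
      if (block_presses %% ratio == 0L) {
        if (t <= duration) { times <- c(times, t); kinds <- c(kinds, "reward") }
        block_rewards <- block_rewards + 1L
        t <- t + policy$post_reward_pause
        if (block_rewards >= rewards_per_block) {
          t_retract <- times[length(times)] + switch_latency
          t_extend <- t_retract + switch_latency
          if (t_retract > duration) break
          times <- c(times, t_retract)
          kinds <- c(kinds, paste0("lever_retract_", side))
          side <- if (side == "left") "right" else "left"
          if (t_extend > duration) break
          times <- c(times, t_extend)
          kinds <- c(kinds, paste0("lever_extend_", side))
          t <- max(t, t_extend)
          block_presses <- 0L; block_rewards <- 0L
        }
      }
    }
  })
  event_log(times, kinds, duration, task_label = "FR5_switch",
            schedule_ratio = ratio, seed = seed)
}

#' Simulate the two-lever FR1 delay session
#'
#' Discrete-trial design: one of the two levers (fair, seeded coin) extends;
#' pressing it causes immediate retraction, pellet delivery exactly 1 s
#' later, and - after a 2 s inter-trial interval - the next random
#' extension. No presses are possible while no lever is out.
#'
#' The lever-selection stream is seeded independently of the presser-policy
#' stream, so changing the policy never changes the lever sequence.
#'
#' @inheritParams simulate_fr_session
#' @param reward_delay Seconds from press to pellet (task value 1.0).
#' @param iti Inter-trial interval in seconds (task value 2.0).
#' @return An [event_log()] with `schedule_ratio = 1`.
#' @export
simulate_two_lever_delay_session <- function(duration,
                                             policy = presser_policy(),
                                             seed = 1L, reward_delay = 1.0,
                                             iti = 2.0) {
  check_positive_scalar(duration, "duration")
  # generous upper bound on trial count for the pre-drawn lever sequence
  max_trials <- ceiling(duration / (reward_delay + iti)) + 2L
  sides <- with_seed(seed + 1000003L, {
    ifelse(stats::runif(max_trials) < 0.5, "left", "right")
  })

  times <- numeric(0); kinds <- character(0)
  with_seed(seed, {
    t_extend <- 0; trial <- 1L
    repeat {
      if (t_extend > duration || trial > max_trials) break
      side <- sides[trial]
      times <- c(times, t_extend)
      kinds <- c(kinds, paste0("lever_extend_", side))
      wait <- next_interval(policy)
      t_press <- t_extend + wait
      if (!is.finite(t_press) || t_press > duration) break
      times <- c(times, t_press, t_press)
      kinds <- c(kinds, paste0("press_", side), paste0("lever_retract_", side))
      t_reward <- t_press + reward_delay
      if (t_reward > duration) break
      times <- c(times, t_reward); kinds <- c(kinds, "reward")
      t_extend <- t_reward + iti
      trial <- trial + 1L
    }
  })
  event_log(times, kinds, duration, task_label = "two_lever_FR1_delay",
            schedule_ratio = 1L, seed = seed)
}

#' Simulate the non-contingent reward session
#'
#' Rewards arrive on a fixed 20 s clock regardless of behavior, each
#' announced by a 1 s cue (white noise) that ends at delivery. No lever is
#' present and no presses are produced.
#'
#' @param duration Session length in seconds.
#' @param seed Integer seed (kept for interface symmetry; the schedule is
#'   deterministic).
#' @param interval Seconds between rewards (task value 20).
#' @param cue_lead Seconds the cue precedes each reward (task value 1).
#' @return An [event_log()].
#' @export
simulate_noncontingent_session <- function(duration, seed = 1L,
                                           interval = 20, cue_lead = 1.0) {
  check_positive_scalar(duration, "duration")
  check_positive_scalar(interval, "interval")
  reward_t <- seq(interval, duration, by = interval)
  if (!length(reward_t)) {
    return(event_log(numeric(0), character(0), duration,
                     task_label = "noncontingent", seed = seed))
  }
  times <- c(reward_t - cue_lead, reward_t, reward_t)
  kinds <- c(rep("cue_on", length(reward_t)),
             rep("cue_off", length(reward_t)),
             rep("reward", length(reward_t)))
  keep <- times >= 0
  event_log(times[keep], kinds[keep], duration,
            task_label = "noncontingent", seed = seed)
}

#' The optogenetic self-stimulation testing protocol
#'
#' The full self-stimulation schedule: eight consecutive daily sessions on
#' each of FR1, FR3 and FR5, then eight extinction sessions, one session
#' per day.
#'
#' @param sessions_per_phase Sessions in each phase (8 in the protocol).
#' @return A data.frame with one row per session-day: `day`, `phase`,
#'   `schedule_ratio` (`NA` during extinction).
#' @export
selfstim_protocol <- function(sessions_per_phase = 8L) {
  sessions_per_phase <- check_count(sessions_per_phase, "sessions_per_phase")
  phases <- c("FR1", "FR3", "FR5", "extinction")
  ratios <- c(1L, 3L, 5L, NA_integer_)
  data.frame(
    day = seq_len(4L * sessions_per_phase),
    phase = rep(phases, each = sessions_per_phase),
    schedule_ratio = rep(ratios, each = sessions_per_phase),
    stringsAsFactors = FALSE)
}

# --- lever availability -----------------------------------------------------

# Intervals during which each lever is extended, derived from a log's
# extend/retract events. Returns a list(left=, right=) of two-column
# matrices (start, end); a lever still out at session end closes at
# `duration`.
lever_intervals <- function(log) {
  stopifnot(inherits(log, "event_log"))
  out <- list()
  for (side in c("left", "right")) {
    ext <- event_times(log, paste0("lever_extend_", side))
    ret <- event_times(log, paste0("lever_retract_", side))
    ends <- numeric(length(ext))
    for (i in seq_along(ext)) {
      after <- ret[ret >= ext[i]]
      # a lever still out at session end stays available through the last
      # sample (closed right endpoint)
      ends[i] <- if (length(after)) after[1] else log$duration + 1e-9
    }
    out[[side]] <- cbind(start = ext, end = ends)
  }
  out
}
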