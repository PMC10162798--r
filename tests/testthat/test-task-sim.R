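det_policy <- function(rate = 30, pause = 0)
  presser_policy(rate, pause, "deterministic")

test_that("fixed-ratio sessions reinforce every ratio-th press", {
  for (ratio in c(1L, 3L, 5L)) {
    log <- simulate_fr_session(ratio, 120, det_policy(30), seed = 1)
    presses <- length(event_times(log, "press_any"))
    rewards <- length(event_times(log, "reward"))
    expect_equal(rewards, floor(presses / ratio))
    expect_true(validate_event_log(log))
  }
  # identity schedule: one reward per press
  log1 <- simulate_fr_session(1, 21, det_policy(30), seed = 1)
  expect_equal(length(event_times(log1, "press_left")), 10)
  expect_equal(length(event_times(log1, "reward")), 10)
  expect_equal(event_times(log1, "reward"),
               event_times(log1, "press_left"))
})

test_that("session events never exceed the session duration", {
  log <- simulate_fr_session(5, 1800, presser_policy(20, 2, "poisson"),
                             seed = 7)
  expect_lte(max(log$events$time_s), 1800)
  expect_gte(min(log$events$time_s), 0)
})

test_that("fr session rejects bad arguments", {
  expect_error(simulate_fr_session(0, 100), class = "opercal_invalid_argument")
  expect_error(simulate_fr_session(5, -1), class = "opercal_invalid_argument")
})

test_that("FR5 switch blocks end after 25 presses and 5 rewards", {
  log <- simulate_fr5_switch_session(600, det_policy(30), seed = 1)
  ev <- log$events
  first_retract <- which(grepl("^lever_retract", ev$kind))[1]
  before <- ev$kind[seq_len(first_retract - 1L)]
  expect_equal(sum(grepl("^press", before)), 25)
  expect_equal(sum(before == "reward"), 5)
})

test_that("FR5 switch lever identities alternate L, R, L, R", {
  log <- simulate_fr5_switch_session(1200, det_policy(60, 0), seed = 2)
  sides <- sub("lever_extend_", "",
               log$events$kind[grepl("^lever_extend", log$events$kind)])
  expect_gte(length(sides), 4)
  expect_equal(sides[1:4], c("left", "right", "left", "right"))
  # presses within each block are on the extended lever only
  expect_true(validate_event_log(log))
})

test_that("two-lever delay task times rewards and extensions exactly", {
  log <- simulate_two_lever_delay_session(600, presser_policy(20, 0), seed = 3)
  ev <- log$events
  presses <- ev$time_s[grepl("^press", ev$kind)]
  rewards <- ev$time_s[ev$kind == "reward"]
  extensions <- ev$time_s[grepl("^lever_extend", ev$kind)]
  expect_equal(rewards, presses[seq_along(rewards)] + 1.0)
  # each extension after the first follows the previous reward by the ITI
  expect_equal(extensions[-1],
               rewards[seq_len(length(extensions) - 1L)] + 2.0)
  # trials partition the session: retraction accompanies every press
  expect_equal(sum(grepl("^lever_retract", ev$kind)), length(presses))
})

test_that("delay-task lever selection is a fair seeded coin", {
  log <- simulate_two_lever_delay_session(4000, det_policy(60), seed = 7)
  sides <- log$events$kind[grepl("^lever_extend", log$events$kind)]
  expect_gte(length(sides), 1000)
  frac_left <- mean(sides == "lever_extend_left")
  expect_lt(abs(frac_left - 0.5), 0.05)
  # lever sequence independent of the presser-policy stream
  log2 <- simulate_two_lever_delay_session(4000, det_policy(30), seed = 7)
  sides2 <- log2$events$kind[grepl("^lever_extend", log2$events$kind)]
  n <- min(length(sides), length(sides2))
  expect_equal(sides[seq_len(n)], sides2[seq_len(n)])
})

test_that("non-contingent sessions reward on a 20 s clock with a 1 s cue", {
  log <- simulate_noncontingent_session(600, 1)
  rewards <- event_times(log, "reward")
  expect_equal(length(rewards), 30)
  expect_equal(rewards, seq(20, 600, by = 20))
  cues <- event_times(log, "cue_on")
  expect_equal(rewards - cues, rep(1.0, 30))
  expect_equal(length(event_times(log, "press_any")), 0)

  short <- simulate_noncontingent_session(20, 1)
  expect_equal(event_times(short, "reward"), 20)
  expect_equal(event_times(short, "cue_on"), 19)
})

test_that("simultaneous events sort extension < press < retraction < cue < reward", {
  log <- event_log(c(5, 5, 5, 5, 0), c("reward", "lever_retract_left",
                                       "press_left", "lever_extend_right",
                                       "lever_extend_left"),
                   duration = 10)
  expect_equal(log$events$kind,
               c("lever_extend_left", "lever_extend_right", "press_left",
                 "lever_retract_left", "reward"))
})

test_that("identical seeds reproduce sessions byte-identically", {
  a <- simulate_fr5_switch_session(300, presser_policy(15, 2, "poisson"),
                                   seed = 11)
  b <- simulate_fr5_switch_session(300, presser_policy(15, 2, "poisson"),
                                   seed = 11)
  expect_identical(a, b)
  d1 <- simulate_two_lever_delay_session(300, presser_policy(10, 0), seed = 4)
  d2 <- simulate_two_lever_delay_session(300, presser_policy(10, 0), seed = 4)
  expect_identical(d1, d2)
})

test_that("the self-stimulation protocol spans 32 session-days", {
  prot <- selfstim_protocol()
  expect_equal(nrow(prot), 32)
  expect_equal(as.vector(table(prot$phase)[c("FR1", "FR3", "FR5",
                                             "extinction")]),
               rep(8L, 4))
  expect_equal(prot$day, 1:32)
})

test_that("event logs round-trip through CSV plus JSON sidecar", {
  log <- simulate_fr_session(3, 200, presser_policy(12, 2, "poisson"),
                             seed = 9)
  path <- file.path(tempdir(), "events.csv")
  write_event_log(log, path)
  back <- read_event_log(path)
  expect_equal(back$events, log$events)
  expect_equal(back$duration, log$duration)
  expect_equal(back$schedule_ratio, log$schedule_ratio)
})
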