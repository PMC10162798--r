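test_that("the standard window yields 60 bins and constant traces bin to c", {
  trace <- rep(2.5, 30 * 60 + 1)
  p <- build_peth(trace, 30, c(10, 20, 30))
  expect_equal(dim(p$matrix), c(3L, 60L))
  expect_true(all(p$matrix == 2.5))
})

test_that("a unit impulse at the event time lands in the bin covering zero", {
  n <- 30 * 60 + 1
  trace <- numeric(n)
  k <- 901L                       # sample at t = 30 s exactly
  trace[k] <- 1
  p <- build_peth(trace, 30, (k - 1) / 30)
  nonzero <- which(p$matrix[1, ] != 0)
  expect_equal(nonzero, 31L)      # bin [0, 0.1): the 31st of 60
})

test_that("events without full window coverage are dropped, not padded", {
  trace <- rnorm(30 * 20 + 1)
  p <- build_peth(trace, 30, c(1.0, 10, 19.5))
  expect_equal(nrow(p$matrix), 1L)
  expect_equal(p$n_dropped, 2L)
  expect_error(build_peth(trace, 30, c(0.5, 19.9)),
               class = "opercal_empty_result")
  expect_error(build_peth(trace, 30, numeric(0)),
               class = "opercal_empty_result")
})

test_that("baseline threshold is the type-7 99th percentile of pooled bins", {
  # constant baseline: threshold equals the constant
  mat <- matrix(0, 5, 60); mat[, 1:20] <- 3
  expect_equal(baseline_threshold(make_peth(mat)), 3)
  # pooled 1..100 -> 99.01 under linear interpolation
  mat2 <- matrix(0, 5, 60)
  mat2[, 1:20] <- matrix(1:100, 5, 20)
  expect_equal(baseline_threshold(make_peth(mat2)), 99.01)
  # pooling is order-free across trials
  mat3 <- mat2[sample(5), ]
  expect_equal(baseline_threshold(make_peth(mat3)),
               baseline_threshold(make_peth(mat2)))
})

test_that("modulation needs three consecutive supra-threshold event bins", {
  base <- matrix(rep(seq(-1, 1, length.out = 20), each = 4), 4, 20)
  mat <- cbind(base, matrix(0, 4, 40))
  # two consecutive hot bins only -> not modulated
  m2 <- mat; m2[, 31:32] <- 5
  r2 <- classify_modulated(make_peth(m2))
  expect_false(r2$is_modulated)
  expect_equal(r2$run_length, 2L)
  # three consecutive -> modulated, with run start reported
  m3 <- mat; m3[, 31:33] <- 5
  r3 <- classify_modulated(make_peth(m3))
  expect_true(r3$is_modulated)
  expect_equal(r3$run_length, 3L)
  expect_equal(r3$run_start_bin, 31L)
  # supra-threshold bins outside the event window do not count
  m4 <- mat; m4[, 40:50] <- 5
  expect_false(classify_modulated(make_peth(m4))$is_modulated)
  expect_true(classify_modulated(make_peth(m4), scan = "full")$is_modulated)
})

test_that("classification agrees exactly with a brute-force scan", {
  for (i in 1:50) {
    p <- random_peth(seed = 1000 + i, n_trials = 3 + i %% 6,
                     inject = i %% 2 == 0)
    got <- classify_modulated(p)
    want <- brute_classify(p)
    expect_identical(got$is_modulated, want$is_modulated)
    expect_identical(got$threshold, want$threshold)
  }
})

test_that("an injected 5-SD response is always detected", {
  for (s in 1:10) {
    p <- random_peth(seed = 2000 + s, n_trials = 10, inject = TRUE)
    expect_true(classify_modulated(p)$is_modulated)
  }
})

test_that("adding a constant to event bins never un-modulates a neuron", {
  for (s in 1:20) {
    p <- random_peth(seed = 3000 + s, n_trials = 6, inject = s %% 2 == 0)
    before <- classify_modulated(p)$is_modulated
    p$matrix[, 26:35] <- p$matrix[, 26:35] + runif(1, 0, 3)
    after <- classify_modulated(p)$is_modulated
    expect_false(before && !after)
  }
})

test_that("shifting trace and events together leaves results unchanged", {
  set.seed(9)
  n <- 30 * 40 + 1
  trace <- rnorm(n)
  ev <- c(10, 15.4, 22.07)
  shift_n <- 45L                  # 1.5 s in samples
  trace2 <- c(numeric(shift_n), trace)
  r1 <- classify_modulated(build_peth(trace, 30, ev))
  r2 <- classify_modulated(build_peth(trace2, 30, ev + shift_n / 30))
  expect_equal(r1$mean_trace, r2$mean_trace, tolerance = 1e-12)
  expect_identical(r1$is_modulated, r2$is_modulated)
  expect_equal(r1$threshold, r2$threshold)
})

test_that("both-lever neurons are excluded from single-lever categories", {
  mk <- function(mod, kind) {
    mat <- matrix(rnorm(4 * 60), 4, 60)
    if (mod) mat[, 31:34] <- mat[, 31:34] + 8
    p <- make_peth(mat)
    p$event_kind <- kind
    classify_modulated(p)
  }
  set.seed(1)
  both <- attribute_lever_modulation(mk(TRUE, "press_left"),
                                     mk(TRUE, "press_right"),
                                     mk(TRUE, "reward"), mk(FALSE, "extension"))
  expect_equal(both$category, "both")
  left <- attribute_lever_modulation(mk(TRUE, "press_left"),
                                     mk(FALSE, "press_right"))
  expect_equal(left$category, "left_only")
  none <- attribute_lever_modulation(mk(FALSE, "press_left"),
                                     mk(FALSE, "press_right"),
                                     mk(FALSE, "reward"), mk(FALSE, "extension"))
  expect_equal(none$category, "unmodulated")
  # mismatched neurons refuse to combine
  a <- mk(TRUE, "press_left"); b <- mk(TRUE, "press_right")
  b$neuron_id <- "n999"
  expect_error(attribute_lever_modulation(a, b),
               class = "opercal_invalid_argument")
})

test_that("percentages report count over population per event kind", {
  mk <- function(id, kind, mod) {
    structure(list(neuron_id = id, event_kind = kind, is_modulated = mod),
              class = "modulation_result")
  }
  res <- c(lapply(1:6, function(i) mk(i, "press", TRUE)),
           lapply(7:10, function(i) mk(i, "press", FALSE)),
           lapply(1:2, function(i) mk(i, "reward", FALSE)))
  pm <- percent_modulated(res, 200)
  expect_equal(pm$percent[pm$event_kind == "press"], 3.0)
  expect_equal(pm$percent[pm$event_kind == "reward"], 0)
  res2 <- lapply(1:40, function(i) mk(i, "press", TRUE))
  expect_equal(percent_modulated(res2, 242)$percent, 100 * 40 / 242,
               tolerance = 1e-9)
  expect_error(percent_modulated(res2, 30),
               class = "opercal_invalid_argument")
})
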