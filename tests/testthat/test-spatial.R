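# small helper: constant-step track visiting given coordinates
toy_track <- function(x, y, rate = 10)
  position_track((seq_along(x) - 1) / rate, x, y, rate)

test_that("occupancy counts every sample into exactly one bin", {
  # stationary animal: all dwell in one bin, sum equals duration
  tr <- toy_track(rep(5, 100), rep(5, 100))
  occ <- compute_occupancy(tr)
  expect_equal(occ$dwell[3, 3], 10)
  expect_equal(sum(occ$dwell), 10)
  # top edge closed: x = 30 lands in the last bin
  tr2 <- toy_track(c(0, 30), c(0, 30))
  occ2 <- compute_occupancy(tr2)
  expect_equal(occ2$counts[1, 1], 1L)
  expect_equal(occ2$counts[15, 15], 1L)
  expect_error(compute_occupancy(toy_track(c(5, 31), c(5, 5))),
               class = "opercal_invalid_argument")
})

test_that("a designed space-filling path gives near-uniform dwell", {
  centers <- as.matrix(expand.grid(x = seq(1, 29, by = 2),
                                   y = seq(1, 29, by = 2)))
  reps <- 4
  tr <- toy_track(rep(centers[, 1], each = reps),
                  rep(centers[, 2], each = reps))
  occ <- compute_occupancy(tr)
  expect_equal(max(occ$dwell) / min(occ$dwell), 1)
  expect_equal(sum(occ$dwell), nrow(centers) * reps / 10)
})

test_that("rate maps are constant for constant activity", {
  set.seed(1)
  tr <- toy_track(runif(4000, 0, 30), runif(4000, 0, 30))
  occ <- compute_occupancy(tr)
  m <- compute_rate_map(rep(2, 4000), tr, occ, transient_sd = 0,
                        min_dwell = 0)
  visited <- !is.na(m$rate)
  expect_true(all(abs(m$rate[visited] - 2 * tr$rate) < 1e-9))
  # conservation: occupancy-weighted mean equals total activity over time
  expect_equal(m$lambda_mean, sum(rep(2, 4000)) / occ$total_time)
})

test_that("activity confined to one visited bin gives one active bin", {
  x <- c(rep(5, 200), rep(15, 200), rep(25, 200))
  tr <- toy_track(x, rep(5, 600))
  act <- c(rep(0, 200), rep(1, 200), rep(0, 200))
  m <- compute_rate_map(act, tr, transient_sd = 0)
  expect_equal(m$active_bins, 1L)
  expect_equal(which(m$active, arr.ind = TRUE)[1, ], c(row = 8L, col = 3L))
})

test_that("spatial information matches closed forms", {
  mkocc <- function(dwell) structure(
    list(dwell = dwell, counts = matrix(1L, nrow(dwell), ncol(dwell)),
         bin_size = 2, rate = 1, total_time = sum(dwell)),
    class = "occupancy_map")
  mkmap <- function(rate) structure(
    list(rate = rate, bin_size = 2), class = "rate_map")
  occ_u <- mkocc(matrix(1, 15, 15))
  # uniform rate over uniform occupancy: zero information
  expect_equal(spatial_information(mkmap(matrix(7, 15, 15)), occ_u), 0)
  # all activity in one of 225 equally occupied bins: log2(225) bits
  one <- matrix(0, 15, 15); one[4, 9] <- 3
  expect_equal(spatial_information(mkmap(one), occ_u), log2(225),
               tolerance = 1e-9)
  # two bins, equal occupancy, rates (2 lambda, 0): exactly 1 bit
  occ2 <- mkocc(matrix(c(5, 5), 1, 2))
  expect_equal(spatial_information(mkmap(matrix(c(4, 0), 1, 2)), occ2), 1,
               tolerance = 1e-12)
  # silent neuron: undefined statistic
  expect_error(spatial_information(mkmap(matrix(0, 15, 15)), occ_u),
               class = "opercal_undefined")
})

test_that("spatial information is invariant to positive rescaling", {
  log <- simulate_noncontingent_session(120, 1)
  tr <- simulate_position_track(log, rate = 30, seed = 2, bias = 0)
  occ <- compute_occupancy(tr)
  set.seed(3)
  act <- pmax(rnorm(nrow(tr$samples)), 0)
  si1 <- spatial_information(compute_rate_map(act, tr, occ), occ)
  si2 <- spatial_information(compute_rate_map(5 * act, tr, occ), occ)
  expect_equal(si1, si2, tolerance = 1e-12)
})

test_that("field center of mass matches point, symmetric and split cases", {
  mkmap <- function(rate) structure(
    list(rate = rate, bin_size = 2), class = "rate_map")
  one <- matrix(NA_real_, 15, 15); one[4, 9] <- 2
  com <- field_com(mkmap(one))
  expect_equal(com$x_com, 7)
  expect_equal(com$y_com, 17)
  # symmetric field about (15, 15)
  g <- outer(1:15, 1:15, function(i, j)
    exp(-(((i - 0.5) * 2 - 15)^2 + ((j - 0.5) * 2 - 15)^2) / 18))
  com_g <- field_com(mkmap(g))
  expect_lt(abs(com_g$x_com - 15), 1)
  expect_lt(abs(com_g$y_com - 15), 1)
  # two equal bins at x = 5 and 25
  two <- matrix(0, 15, 15); two[3, 8] <- 1; two[13, 8] <- 1
  expect_equal(field_com(mkmap(two))$x_com, 15)
  expect_error(field_com(mkmap(matrix(0, 15, 15))),
               class = "opercal_empty_result")
  # translation equivariance: shifting the field shifts the COM equally
  sh <- matrix(0, 15, 15); sh[5, 8] <- 1; sh[15, 8] <- 1
  expect_equal(field_com(mkmap(sh))$x_com, 15 + 4)
})

test_that("two active bins never qualify as spatial however large the SI", {
  x <- rep(seq(1, 29, by = 2), each = 40)
  set.seed(4)
  tr <- toy_track(rep(x, 15), rep(rep(seq(1, 29, by = 2), each = 40 * 15)))
  act <- as.numeric(tr$samples$x_cm < 2 & tr$samples$y_cm < 4)
  r <- shuffle_test(act, tr, n_shuffles = 50, min_shift = 60, seed = 5,
                    transient_sd = 0)
  expect_lte(r$active_bins, 2)
  expect_false(r$eligible)
  expect_false(r$is_spatial)
  expect_gt(r$si, 1)
})

test_that("a strong place cell is flagged spatial", {
  log <- simulate_noncontingent_session(600, 1)
  tr <- simulate_position_track(log, rate = 30, seed = 2, bias = 0)
  occ <- compute_occupancy(tr)
  truth <- generate_population(10, c(place = 1), baseline_rate = 0.1,
                               place_params = list(width = 4), seed = 5)
  tm <- synthesize_traces(truth, log, tr, seed = 6)
  det <- vapply(1:10, function(j)
    shuffle_test(tm$values[j, ], tr, occ, n_shuffles = 200,
                 seed = 300 + j)$is_spatial, logical(1))
  expect_gte(mean(det), 0.8)
})

test_that("identical activity in both epochs gives zero COM shift", {
  log <- simulate_fr5_switch_session(600,
                                     presser_policy(12, 2, "poisson"),
                                     seed = 1)
  n <- 600 * 30 + 1
  # periodic position pattern identical in structure across epochs
  x <- 15 + 10 * sin(2 * pi * (0:(n - 1)) / 300)
  y <- 15 + 10 * cos(2 * pi * (0:(n - 1)) / 300)
  tr <- position_track((0:(n - 1)) / 30, x, y, 30)
  act <- matrix(as.numeric(x > 20), 1, n)
  tm <- trace_matrix(act, 30)
  cs <- switch_com_shift(tm, tr, log, transient_sd = 0,
                         activity_mode = "transients")
  expect_lt(abs(cs$delta_x), 0.5)
})

test_that("a lever with no active time yields missing values, not errors", {
  log <- event_log(c(0, 10, 10, 11), c("lever_extend_left", "press_left",
                                       "lever_retract_left", "reward"),
                   duration = 60, schedule_ratio = 1L)
  expect_error(switch_com_shift(trace_matrix(matrix(1, 1, 601), 10),
                                toy_track(rep(5, 601), rep(5, 601)), log),
               class = "opercal_invalid_argument")
})
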