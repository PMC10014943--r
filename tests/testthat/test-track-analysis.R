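test_that("instantaneous speed matches a direct displacement loop", {
  tr <- track(0:10, rep(1, 11), rep(2, 11))
  expect_identical(instantaneous_speed(tr), 0)
  tr2 <- track(0:5, 2 * (0:5), rep(0, 6))
  expect_equal(instantaneous_speed(tr2), 2, tolerance = 1e-14)
  set.seed(10)
  tr3 <- track(seq(0, 18, by = 2), cumsum(rnorm(10)), cumsum(rnorm(10)))
  manual <- 0
  for (i in 1:9) {
    manual <- manual + sqrt((tr3$x[i + 1] - tr3$x[i])^2 +
                            (tr3$y[i + 1] - tr3$y[i])^2) / 2
  }
  expect_equal(instantaneous_speed(tr3), manual / 9, tolerance = 1e-12)
  expect_error(track(0, 1, 1), "at least 2")
})

test_that("MSD is origin-referenced and exact for ballistic motion", {
  tr <- track(0:20, rep(0, 21), rep(0, 21))
  expect_true(all(msd(tr)$msd == 0))
  v <- 1.5
  trb <- track(0:20, v * (0:20), rep(0, 21))
  expect_equal(msd(trb)$msd, v^2 * (0:20)^2, tolerance = 1e-12)
  set.seed(2)
  trr <- track(0:30, cumsum(rnorm(31)), cumsum(rnorm(31)))
  manual <- (trr$x - trr$x[1])^2 + (trr$y - trr$y[1])^2
  expect_identical(msd(trr)$msd, manual)
})

test_that("alpha is 2 for ballistic and 1 for linear-MSD tracks", {
  trb <- gen_track("ballistic", n = 300, speed = 2, seed = 4)
  a <- alpha_value(trb)
  expect_equal(a$alpha, 2, tolerance = 1e-8)
  expect_true(all(abs(stats::na.omit(a$per_segment) - 2) < 1e-8))
  # constructed track with MSD exactly proportional to t at the samples:
  # radial spoke pattern x = sqrt(t) along one axis
  tt <- 0:199
  trl <- track(tt, sqrt(tt), rep(0, 200))
  expect_equal(alpha_value(trl, window = 200)$alpha, 1, tolerance = 1e-8)
})

test_that("random walks give diffusive alpha near 1 (Monte Carlo)", {
  alphas <- vapply(1:40, function(s) {
    alpha_value(gen_track("brownian", n = 2000, seed = s))$alpha
  }, numeric(1))
  expect_gt(mean(alphas), 0.9)
  expect_lt(mean(alphas), 1.1)
})

test_that("directionality ratio handles straight, bent and closed paths", {
  trs <- track(0:10, 0:10, rep(0, 11))
  expect_equal(directionality_ratio(trs), 1, tolerance = 1e-12)
  out_back <- track(0:10, c(0:5, 4:0), rep(0, 11))
  expect_equal(directionality_ratio(out_back), 0, tolerance = 1e-12)
  bent <- track(0:2, c(0, 1, 1), c(0, 0, 1))
  expect_equal(directionality_ratio(bent), sqrt(2) / 2, tolerance = 1e-12)
  expect_error(directionality_ratio(track(0:3, rep(0, 4), rep(0, 4))),
               "stationary")
})

test_that("DR stays in [0,1] and is 1 only for collinear monotone paths", {
  set.seed(77)
  for (i in 1:25) {
    tr <- gen_track(sample(c("brownian", "ballistic", "piecewise_ballistic"), 1),
                    n = 200, turn_times = c(60, 120), seed = i)
    dr <- directionality_ratio(tr)
    expect_gte(dr, 0); expect_lte(dr, 1 + 1e-12)
  }
})

test_that("rolling DR matches per-window recomputation and dips at a turn", {
  tr <- gen_track("piecewise_ballistic", n = 301, turn_times = 150,
                  turn_angles = 120, seed = 9)
  rd <- rolling_dr(tr, window = 50)
  # direct recomputation of a few windows
  for (s in c(1, 40, 100)) {
    e <- s + 50
    xs <- tr$x[s:e]; ys <- tr$y[s:e]
    D <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
    d <- sqrt((xs[51] - xs[1])^2 + (ys[51] - ys[1])^2)
    expect_equal(rd$dr[s], d / D, tolerance = 1e-12)
  }
  # minimum attained when the window is centred on the turn
  expect_lt(abs(rd$time[which.min(rd$dr)] - 150), 25)
  straight <- gen_track("ballistic", n = 200, seed = 1)
  expect_true(all(rolling_dr(straight, window = 50)$dr > 0.999))
  expect_error(rolling_dr(straight, window = 500), "longer than track")
})

test_that("event detection recovers constructed turns and refuses inactive tracks", {
  tr <- gen_track("piecewise_ballistic", n = 401, turn_times = c(150, 250),
                  turn_angles = 120, seed = 21)
  ev <- detect_events(tr, window = 50)
  expect_length(ev$times, 2)
  expect_lt(abs(ev$times[1] - 150), 25)
  expect_lt(abs(ev$times[2] - 250), 25)
  ball <- gen_track("ballistic", n = 300, seed = 3)
  expect_length(detect_events(ball, window = 50)$times, 0)
  lazy <- gen_track("stationary_jitter", n = 300, seed = 3)
  expect_error(detect_events(lazy, window = 50), "inactive")
})

test_that("event detection has high recall and precision on a synthetic suite", {
  # piecewise-ballistic tracks, turn angles >= 60 degrees, legs >= 2 windows
  hits <- 0; false_pos <- 0; total_true <- 0
  for (s in 1:12) {
    set.seed(100 + s)
    turns <- c(130, 260)
    ang <- sample(c(60, 90, 120, 150), 2, replace = TRUE) *
      sample(c(-1, 1), 2, replace = TRUE)
    tr <- gen_track("piecewise_ballistic", n = 401, turn_times = turns,
                    turn_angles = ang, noise_sd = 0.15, seed = 100 + s)
    ev <- detect_events(tr, window = 50)
    total_true <- total_true + length(turns)
    matched <- rep(FALSE, length(turns))
    for (et in ev$times) {
      j <- which(abs(turns - et) <= 25 & !matched)
      if (length(j)) matched[j[1]] <- TRUE else false_pos <- false_pos + 1
    }
    hits <- hits + sum(matched)
  }
  recall <- hits / total_true
  precision <- hits / (hits + false_pos)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("periods of directedness in piecewise tracks carry high alpha", {
  tr <- gen_track("piecewise_ballistic", n = 501,
                  turn_times = c(120, 240, 360), turn_angles = 120,
                  noise_sd = 0.05, seed = 31)
  ev <- detect_events(tr, window = 50)
  pa <- stats::na.omit(ev$period_alpha)
  expect_true(all(pa > 1.4))
})

test_that("activity classes follow the alpha and DR thresholds", {
  expect_identical(classify_activity(1.0, 0.9, "cpm"), "inactive")
  expect_identical(classify_activity(2.0, 0.95, "cpm"), "directed")
  expect_identical(classify_activity(2.0, 0.5, "cpm"), "oscillatory")
  expect_identical(classify_activity(1.4, 0.8, "cpm"), "directed")  # boundaries up
  expect_identical(classify_activity(1.8, NULL, "experimental"), "active")
})

test_that("classification is invariant to rigid motions of the track", {
  tr <- gen_track("piecewise_ballistic", n = 301, turn_times = 150,
                  turn_angles = 100, noise_sd = 0.1, seed = 8)
  th <- 0.7
  rot <- track(tr$time, cos(th) * tr$x - sin(th) * tr$y + 12,
               sin(th) * tr$x + cos(th) * tr$y - 5)
  expect_equal(alpha_value(tr)$alpha, alpha_value(rot)$alpha, tolerance = 1e-9)
  expect_equal(directionality_ratio(tr), directionality_ratio(rot),
               tolerance = 1e-9)
})

test_that("event-count normalization is a z-score against the WT sample", {
  expect_equal(normalize_event_counts(6, c(2, 4)), 3 / sqrt(2),
               tolerance = 1e-12)
  wt <- c(3, 5, 7, 5)
  expect_equal(mean(normalize_event_counts(wt, wt)), 0, tolerance = 1e-12)
  expect_equal(normalize_event_counts(mean(wt), wt), 0, tolerance = 1e-12)
  expect_error(normalize_event_counts(1, c(4, 4)), "spread")
  expect_error(normalize_event_counts(1, 4), ">= 2")
})

test_that("tracks round-trip through delimited text", {
  tr <- gen_track("brownian", n = 50, seed = 12)
  f <- tempfile(fileext = ".csv")
  write_track(tr, f)
  back <- read_tracks(f, source = "cpm")[[1]]
  expect_equal(back$x, tr$x, tolerance = 1e-6)
  expect_equal(back$y, tr$y, tolerance = 1e-6)
})
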