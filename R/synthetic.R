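#' Generate a synthetic track with known ground truth
#'
#' Fixture generator emulating the migration phenotypes seen in single-cell
#' experiments and lattice simulations: `"stationary_jitter"` (sub-pixel
#' noise around a fixed point), `"brownian"` (independent Gaussian
#' increments per axis, diffusive, alpha near 1), `"ballistic"` (constant
#' velocity, alpha = 2), and `"piecewise_ballistic"` (ballistic legs
#' separated by abrupt turns at known times — the piecewise-directed
#' phenotype event detection is built to recover).
#'
#' @param kind track type (above).
#' @param n number of points.
#' @param dt sampling interval.
#' @param speed speed of ballistic motion (distance/time).
#' @param diffusion per-axis increment scale for brownian/jitter kinds
#'   (distance per sqrt(time)).
#' @param turn_times times of direction changes (piecewise kind); must be
#'   strictly increasing and interior to the track.
#' @param turn_angles turn angles in degrees (recycled to match
#'   `turn_times`).
#' @param noise_sd additive positional noise on ballistic legs.
#' @param seed random seed (reproducible).
#' @param source source tag for the returned track.
#' @return a `racpax_track` with attribute `ground_truth` (list with
#'   `kind`, `turn_times`, `true_alpha_regime`).
#' @export
gen_track <- function(kind = c("brownian", "ballistic", "piecewise_ballistic",
                               "stationary_jitter"),
                      n = 500, dt = 1, speed = 1, diffusion = 1,
                      turn_times = NULL, turn_angles = 120, noise_sd = 0,
                      seed = 1, source = "cpm") {
  kind <- match.arg(kind)
  if (n < 2) stop("invalid spec: need n >= 2", call. = FALSE)
  times <- (seq_len(n) - 1) * dt
  if (kind == "piecewise_ballistic") {
    if (is.null(turn_times) || !length(turn_times)) {
      stop("invalid spec: piecewise_ballistic needs turn_times", call. = FALSE)
    }
    if (is.unsorted(turn_times, strictly = TRUE) ||
        min(turn_times) <= min(times) || max(turn_times) >= max(times)) {
      stop("invalid spec: turn times must be strictly increasing and interior",
           call. = FALSE)
    }
  }
  set.seed(seed)
  gt <- list(kind = kind, turn_times = turn_times)
  if (kind == "stationary_jitter") {
    sc <- diffusion * sqrt(dt) * 0.1
    x <- cumsum(c(0, stats::rnorm(n - 1, 0, sc)))
    y <- cumsum(c(0, stats::rnorm(n - 1, 0, sc)))
    gt$true_alpha_regime <- "diffusive"
  } else if (kind == "brownian") {
    sc <- diffusion * sqrt(dt)
    x <- cumsum(c(0, stats::rnorm(n - 1, 0, sc)))
    y <- cumsum(c(0, stats::rnorm(n - 1, 0, sc)))
    gt$true_alpha_regime <- "diffusive"
  } else {
    angles0 <- stats::runif(1, 0, 360)
    if (kind == "ballistic") {
      theta <- rep(angles0, n - 1)
      gt$true_alpha_regime <- "ballistic"
    } else {
      turn_angles <- rep_len(turn_angles, length(turn_times))
      theta <- numeric(n - 1)
      cur <- angles0
      k <- 1
      for (i in seq_len(n - 1)) {
        while (k <= length(turn_times) && times[i] >= turn_times[k]) {
          cur <- cur + turn_angles[k]
          k <- k + 1
        }
        theta[i] <- cur
      }
      gt$true_alpha_regime <- "piecewise_ballistic"
    }
    rad <- theta * pi / 180
    x <- cumsum(c(0, speed * dt * cos(rad)))
    y <- cumsum(c(0, speed * dt * sin(rad)))
    if (noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, noise_sd)
      y <- y + stats::rnorm(n, 0, noise_sd)
    }
  }
  tr <- track(times, x, y, source)
  attr(tr, "ground_truth") <- gt
  tr
}

#' Generate a translating-blob mask sequence with known activity
#'
#' A disc or square of fixed size translating a whole number of pixels per
#' frame. For a square of side `s` moving 1 px/frame along an axis the
#' expected membrane activity is exactly `2 s` per frame.
#'
#' @param shape `"square"` or `"disk"`.
#' @param size square side or disc radius (pixels).
#' @param displacement per-frame displacement `c(dx, dy)` in whole pixels.
#' @param n_frames number of frames.
#' @param img_size image dimensions `c(rows, cols)`.
#' @param noise_frac fraction of pixels flipped per frame (salt noise on the
#'   mask; 0 for exact fixtures).
#' @param seed random seed.
#' @return list with `masks` (list of logical matrices) and
#'   `expected_activity` (per-frame series; exact only for `noise_frac = 0`).
#' @export
gen_mask_sequence <- function(shape = c("square", "disk"), size = 10,
                              displacement = c(1, 0), n_frames = 10,
                              img_size = c(64, 64), noise_frac = 0, seed = 1) {
  shape <- match.arg(shape)
  set.seed(seed)
  draw <- function(cx, cy) {
    m <- matrix(FALSE, img_size[1], img_size[2])
    if (shape == "square") {
      rows <- (round(cx)):(round(cx) + size - 1)
      cols <- (round(cy)):(round(cy) + size - 1)
      stopifnot(min(rows) >= 1, max(rows) <= img_size[1],
                min(cols) >= 1, max(cols) <= img_size[2])
      m[rows, cols] <- TRUE
    } else {
      rr <- row(m) - cx; cc <- col(m) - cy
      m[rr^2 + cc^2 <= size^2] <- TRUE
    }
    m
  }
  cx0 <- ceiling(img_size[1] / 4); cy0 <- ceiling(img_size[2] / 4)
  masks <- lapply(seq_len(n_frames) - 1, function(k) {
    m <- draw(cx0 + k * displacement[1], cy0 + k * displacement[2])
    if (noise_frac > 0) {
      flip <- sample(length(m), round(noise_frac * length(m)))
      m[flip] <- !m[flip]
    }
    m
  })
  expected <- if (noise_frac == 0) activity_series(masks) else NULL
  list(masks = masks, expected_activity = expected)
}

#' Generate a synthetic metrics table for classifier tests
#'
#' Three Gaussian clusters in the four-metric feature space (speed, alpha,
#' DR, event count), one per paxillin condition, with configurable
#' separation. A stand-in for lattice-simulation output when testing the
#' classifier in isolation.
#'
#' @param n_per_condition cells per condition.
#' @param separation multiple of the within-cluster spread separating the
#'   condition means (0 = identical distributions).
#' @param seed random seed.
#' @return data frame with `condition` and the four metric columns.
#' @export
gen_condition_table <- function(n_per_condition = 20, separation = 3, seed = 1) {
  set.seed(seed)
  conds <- c("WT", "S273A", "S273D")
  base <- list(mean_speed = 1.0, mean_alpha = 1.5, dr = 0.5, n_events = 4)
  sds <- c(mean_speed = 0.05, mean_alpha = 0.1, dr = 0.08, n_events = 1.2)
  # condition offsets in units of the within-cluster sd, per metric
  dir <- rbind(WT = c(0, 0, 0, 0),
               S273A = c(-1, -1, -0.5, -1),
               S273D = c(1, 1, 0.5, 0.3))
  out <- do.call(rbind, lapply(seq_along(conds), function(i) {
    mu <- unlist(base) + separation * dir[i, ] * sds
    data.frame(
      condition = conds[i],
      mean_speed = stats::rnorm(n_per_condition, mu[1], sds[1]),
      mean_alpha = stats::rnorm(n_per_condition, mu[2], sds[2]),
      dr = pmin(pmax(stats::rnorm(n_per_condition, mu[3], sds[3]), 0), 1),
      n_events = pmax(round(stats::rnorm(n_per_condition, mu[4], sds[4])), 0),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
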