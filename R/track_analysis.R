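#' Cell migration track
#'
#' A track is a uniformly sampled centroid trajectory. Times must be
#' strictly increasing with a constant interval; coordinates are in
#' micrometres (experimental) or lattice units (simulated).
#'
#' @param time numeric vector of sample times (uniform interval).
#' @param x,y coordinates.
#' @param source `"cpm"` (simulated) or `"experimental"`; sets the default
#'   analysis windows.
#' @return a `racpax_track` (data frame with attributes `source`, `dt`).
#' @export
track <- function(time, x, y, source = c("cpm", "experimental")) {
  source <- match.arg(source)
  if (length(time) < 2) stop("a track needs at least 2 points", call. = FALSE)
  if (any(!is.finite(time)) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite track data", call. = FALSE)
  }
  dts <- diff(time)
  if (any(dts <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (diff(range(dts)) > 1e-8 * max(dts)) {
    stop("sampling interval must be uniform", call. = FALSE)
  }
  structure(data.frame(time = time, x = x, y = y),
            source = source, dt = dts[1],
            class = c("racpax_track", "data.frame"))
}

#' Read tracks from delimited text
#'
#' Expects a header with columns `time`, `x`, `y` and optionally `cell`
#' (long format, several cells per file).
#'
#' @param file path to a delimited text file (separator auto-detected among
#'   comma and tab).
#' @param source passed to [track()].
#' @return a list of `racpax_track` objects (named by cell id when present).
#' @export
read_tracks <- function(file, source = c("cpm", "experimental")) {
  source <- match.arg(source)
  first <- readLines(file, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep)
  need <- c("time", "x", "y")
  if (!all(need %in% names(d))) {
    stop("track file must have columns time, x, y", call. = FALSE)
  }
  if ("cell" %in% names(d)) {
    out <- lapply(split(d, d$cell), function(g) {
      g <- g[order(g$time), ]
      track(g$time, g$x, g$y, source)
    })
    out
  } else {
    list(track(d$time, d$x, d$y, source))
  }
}

#' Write a track to delimited text
#' @param t a `racpax_track`.
#' @param file output path.
#' @export
write_track <- function(t, file) {
  utils::write.csv(as.data.frame(t)[c("time", "x", "y")], file,
                   row.names = FALSE, quote = FALSE)
}

default_window <- function(t) {
  # alpha segments and rolling-DR windows: 50 steps for simulated cells,
  # 20 min (alpha) / 60 min (rolling DR) for experimental recordings
  if (attr(t, "source") == "cpm") {
    list(alpha = 50 * attr(t, "dt"), dr = 50 * attr(t, "dt"))
  } else {
    list(alpha = 20, dr = 60)
  }
}

#' Mean instantaneous speed
#'
#' Mean over consecutive samples of the displacement divided by the
#' sampling interval.
#'
#' @param t a `racpax_track`.
#' @return mean speed (distance per time unit).
#' @export
instantaneous_speed <- function(t) {
  stopifnot(inherits(t, "racpax_track"))
  if (nrow(t) < 2) stop("insufficient data: need >= 2 points", call. = FALSE)
  steps <- sqrt(diff(t$x)^2 + diff(t$y)^2)
  mean(steps / attr(t, "dt"))
}

#' Mean-square displacement series
#'
#' Origin-referenced MSD: squared distance from the first point at each
#' sample time (not time-lag-averaged).
#'
#' @param t a `racpax_track`.
#' @return data frame with `time` and `msd`.
#' @export
msd <- function(t) {
  stopifnot(inherits(t, "racpax_track"))
  data.frame(time = t$time,
             msd = (t$x - t$x[1])^2 + (t$y - t$y[1])^2)
}

# OLS slope of log(MSD) vs log(lag) within one segment; origin at the
# segment's first point, zero-MSD lags skipped. NA when under-determined.
segment_alpha <- function(x, y, time) {
  m <- (x - x[1])^2 + (y - y[1])^2
  lag <- time - time[1]
  ok <- lag > 0 & m > 0
  if (sum(ok) < 2) return(NA_real_)
  lx <- log(lag[ok]); ly <- log(m[ok])
  stats::cov(lx, ly) / stats::var(lx)
}

#' MSD exponent (alpha-value) of a track
#'
#' The track is cut into contiguous non-overlapping segments of duration
#' `window`; within each segment the MSD is measured from the segment start
#' and the slope of log MSD versus log lag time is estimated by ordinary
#' least squares. The track's alpha-value is the mean over segments.
#' Ballistic tracks give exactly 2, tracks with linear MSD give 1.
#'
#' @param t a `racpax_track`.
#' @param window segment duration (same units as `time`); default 50 steps
#'   for simulated, 20 min for experimental tracks.
#' @return list with `alpha` (mean) and `per_segment` (vector).
#' @export
alpha_value <- function(t, window = NULL) {
  stopifnot(inherits(t, "racpax_track"))
  if (is.null(window)) window <- default_window(t)$alpha
  dt <- attr(t, "dt")
  seg_pts <- max(3, round(window / dt))
  n <- nrow(t)
  starts <- seq(1, n - 2, by = seg_pts)
  per <- vapply(starts, function(s) {
    e <- min(s + seg_pts, n)
    if (e - s + 1 < 3) return(NA_real_)
    segment_alpha(t$x[s:e], t$y[s:e], t$time[s:e])
  }, numeric(1))
  if (all(is.na(per))) {
    stop("undefined alpha: all segments degenerate (zero MSD)", call. = FALSE)
  }
  if (anyNA(per)) warning(sum(is.na(per)), " segment(s) skipped (zero MSD)")
  list(alpha = mean(per, na.rm = TRUE), per_segment = per)
}

#' Directionality ratio
#'
#' Net displacement `d` (start to end) over total path length `D`:
#' `DR = d / D`, in `[0, 1]`. 1 for a straight monotone path, near 0 for a
#' path returning to its start.
#'
#' @param t a `racpax_track`.
#' @return the directionality ratio.
#' @export
directionality_ratio <- function(t) {
  stopifnot(inherits(t, "racpax_track"))
  D <- sum(sqrt(diff(t$x)^2 + diff(t$y)^2))
  if (D == 0) stop("undefined DR: stationary track (zero path length)", call. = FALSE)
  d <- sqrt((t$x[nrow(t)] - t$x[1])^2 + (t$y[nrow(t)] - t$y[1])^2)
  d / D
}

#' Rolling-window directionality ratio
#'
#' DR of each window of duration `window`, indexed by the window centre and
#' shifted by one sampling interval at a time. During a period of directed
#' motion the rolling DR is high; it dips when the window straddles an
#' abrupt change of direction, with the minimum attained when the window is
#' centred on the turn.
#'
#' @param t a `racpax_track`.
#' @param window window duration; default 50 steps (simulated) or 60 min
#'   (experimental).
#' @return data frame with `time` (window centre) and `dr`.
#' @export
rolling_dr <- function(t, window = NULL) {
  stopifnot(inherits(t, "racpax_track"))
  if (is.null(window)) window <- default_window(t)$dr
  dt <- attr(t, "dt")
  w_pts <- round(window / dt)
  n <- nrow(t)
  if (w_pts >= n) stop("window longer than track", call. = FALSE)
  starts <- seq_len(n - w_pts)
  dr <- vapply(starts, function(s) {
    e <- s + w_pts
    xs <- t$x[s:e]; ys <- t$y[s:e]
    D <- sum(sqrt(diff(xs)^2 + diff(ys)^2))
    if (D == 0) return(NA_real_)
    sqrt((xs[length(xs)] - xs[1])^2 + (ys[length(ys)] - ys[1])^2) / D
  }, numeric(1))
  data.frame(time = (t$time[starts] + t$time[starts + w_pts]) / 2, dr = dr)
}

# prominence of a local minimum of series s at index i: smaller of the rises
# to the highest point between i and the nearest deeper minimum (or end) on
# each side
min_prominence <- function(s, i) {
  lower_left <- which(s[seq_len(i - 1)] < s[i])
  l <- if (length(lower_left)) max(lower_left) else 1
  lower_right <- which(s[(i + 1):length(s)] < s[i])
  r <- if (length(lower_right)) i + min(lower_right) else length(s)
  min(max(s[l:i]) - s[i], max(s[i:r]) - s[i])
}

#' Detect events of abrupt directionality change
#'
#' Computes the rolling DR, smooths it by locally weighted regression
#' (non-frequency-based), and reports pronounced dips: local minima with
#' prominence at least `prominence`, value below `dip_level`, separated by
#' at least half a window. Detection is only meaningful for active tracks;
#' an inactive track (alpha below the activity threshold) is refused.
#'
#' @param t a `racpax_track`.
#' @param window rolling-DR window duration (defaults as [rolling_dr()]).
#' @param span loess span as a fraction of the series length.
#' @param prominence minimum dip prominence (DR units).
#' @param dip_level only minima below this DR level are events (a turn of
#'   60 degrees between straight legs dips the windowed DR to about 0.87,
#'   so the default admits turns of 60 degrees and sharper).
#' @param alpha_threshold activity threshold on the track's alpha-value.
#' @param force bypass the activity check (for synthetic ground-truth runs).
#' @return an `event_list`: list with `times`, `period_alpha` (alpha of each
#'   inter-event period of directedness), and the smoothed DR series.
#' @export
detect_events <- function(t, window = NULL, span = 0.15, prominence = 0.1,
                          dip_level = 0.9, alpha_threshold = 1.4,
                          force = FALSE) {
  stopifnot(inherits(t, "racpax_track"))
  if (!force) {
    a <- alpha_value(t)$alpha
    if (a < alpha_threshold) {
      stop("inactive track (alpha = ", round(a, 3), " < ", alpha_threshold,
           "): event detection applies to active tracks only", call. = FALSE)
    }
  }
  if (is.null(window)) window <- default_window(t)$dr
  rd <- rolling_dr(t, window)
  ok <- is.finite(rd$dr)
  s <- rd$dr; s[!ok] <- 1  # stationary windows cannot be dips
  fit <- stats::lowess(rd$time, s, f = span)
  sm <- fit$y
  mins <- local_minima(sm)
  if (length(mins)) {
    keep <- vapply(mins, function(i) {
      sm[i] < dip_level && min_prominence(sm, i) >= prominence
    }, logical(1))
    mins <- mins[keep]
  }
  # enforce separation of at least half a window, keeping the deeper dip
  if (length(mins) > 1) {
    sel <- mins[1]
    for (i in mins[-1]) {
      if (rd$time[i] - rd$time[sel[length(sel)]] < window / 2) {
        if (sm[i] < sm[sel[length(sel)]]) sel[length(sel)] <- i
      } else sel <- c(sel, i)
    }
    mins <- sel
  }
  ev_times <- rd$time[mins]
  # alpha over each period of directedness (between consecutive events,
  # including track start and end as period boundaries)
  bounds <- c(min(t$time), ev_times, max(t$time))
  period_alpha <- vapply(seq_len(length(bounds) - 1), function(i) {
    sel <- t$time >= bounds[i] & t$time <= bounds[i + 1]
    if (sum(sel) < 3) return(NA_real_)
    segment_alpha(t$x[sel], t$y[sel], t$time[sel])
  }, numeric(1))
  structure(list(times = ev_times, period_alpha = period_alpha,
                 dr_time = rd$time, dr_raw = rd$dr, dr_smooth = sm),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("%d directionality-change events", length(x$times)))
  if (length(x$times)) cat(" at t =", paste(round(x$times, 1), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Activity classification from track metrics
#'
#' Tracks with alpha-value below 1.4 are inactive. Active simulated cells
#' are split by whole-track DR: directed at or above 0.8, oscillatory
#' below. Experimental cells are labelled inactive/active only. Boundary
#' values are assigned to the upper class.
#'
#' @param alpha mean alpha-value of the track.
#' @param dr whole-track directionality ratio (simulated cells).
#' @param source `"cpm"` or `"experimental"`.
#' @param alpha_threshold,dr_threshold class boundaries.
#' @return character label.
#' @export
classify_activity <- function(alpha, dr = NULL,
                              source = c("cpm", "experimental"),
                              alpha_threshold = 1.4, dr_threshold = 0.8) {
  source <- match.arg(source)
  if (is.na(alpha)) return(NA_character_)
  if (alpha < alpha_threshold) return("inactive")
  if (source == "experimental") return("active")
  if (is.null(dr) || is.na(dr)) stop("DR needed to subclassify active simulated cells",
                                     call. = FALSE)
  if (dr >= dr_threshold) "directed" else "oscillatory"
}

#' Normalize event counts against the wild-type distribution
#'
#' `(count - mean(WT counts)) / sd(WT counts)` with the sample (n-1)
#' standard deviation. The WT condition's mean normalized value is 0 by
#' construction.
#'
#' @param counts event counts to normalize.
#' @param reference WT event counts (length >= 2, nonzero spread).
#' @return normalized values.
#' @export
normalize_event_counts <- function(counts, reference) {
  if (length(reference) < 2) {
    stop("need >= 2 reference (WT) counts", call. = FALSE)
  }
  s <- stats::sd(reference)
  if (s == 0) stop("zero spread in the WT event-count distribution", call. = FALSE)
  (counts - mean(reference)) / s
}

#' Full metrics record for one track
#'
#' Computes the classifier's feature set: mean instantaneous speed, mean
#' alpha-value, whole-track DR and number of directionality-change events
#' (0 for inactive tracks, which are not event-detected), plus the activity
#' class.
#'
#' @param t a `racpax_track`.
#' @param ... passed to [detect_events()].
#' @return one-row data frame (`mean_speed`, `mean_alpha`, `dr`, `n_events`,
#'   `activity_class`).
#' @export
track_metrics <- function(t, ...) {
  sp <- instantaneous_speed(t)
  a <- alpha_value(t)$alpha
  dr <- directionality_ratio(t)
  cls <- classify_activity(a, dr, attr(t, "source"))
  nev <- if (cls == "inactive") 0L else length(detect_events(t, ...)$times)
  data.frame(mean_speed = sp, mean_alpha = a, dr = dr, n_events = nev,
             activity_class = cls, stringsAsFactors = FALSE)
}
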