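#' Scaled concentration of active PAK
#'
#' Active (RacGTP-bound) PAK as a function of active Rac, through the
#' GIT-PIX-PAK complex equilibria:
#' \deqn{K = \frac{\alpha_R R}{(1 + k_X PIX)(1 + \alpha_R R) +
#'   k_G k_X GIT \cdot PIX / (1 + k_X PIX + 3/(1+R))}.}
#' `K` is zero at `R = 0`, strictly increasing in `R`, and saturates below
#' `1 / (1 + k_X PIX)`.
#'
#' @param R scaled active-Rac concentration (vectorised, `>= 0`).
#' @param p a [kinetic_params()] object.
#' @return scaled active-PAK concentration, same length as `R`.
#' @export
pak_active_fraction <- function(R, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(!is.finite(R))) stop("R must be finite", call. = FALSE)
  if (any(R < 0)) stop("R must be nonnegative", call. = FALSE)
  p$alpha_R * R / ((1 + p$k_X * p$PIX) * (1 + p$alpha_R * R) +
    p$k_G * p$k_X * p$GIT * p$PIX / (1 + p$k_X * p$PIX + 3 / (1 + R)))
}

#' GIT-PIX-PAK complex-dependent Rac activation rate
#'
#' The feedback of phosphorylated paxillin onto Rac activation:
#' \deqn{I_K^* = I_K \left(1 - \frac{1}{1.5 + k_X PIX +
#'   k_G k_X k_C GIT \cdot PIX \cdot Pax_{tot} P}\right).}
#' Monotone nondecreasing in `P`, bounded in `[0, I_K)`.
#'
#' @param P scaled phosphorylated-paxillin concentration (vectorised, `>= 0`).
#' @param p a [kinetic_params()] object.
#' @return activation rate, same length as `P`.
#' @export
git_pix_pak_activation <- function(P, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(!is.finite(P))) stop("P must be finite", call. = FALSE)
  if (any(P < 0)) stop("P must be nonnegative", call. = FALSE)
  p$I_K * (1 - 1 / (1.5 + p$k_X * p$PIX +
    p$k_G * p$k_X * p$k_C * p$GIT * p$PIX * p$Pax_tot * P))
}

#' Quasi-steady-state active Rho
#'
#' Active Rho slaved to Rac under the timescale-separation assumption:
#' \deqn{\rho = \frac{I_\rho L_R^n}{I_\rho L_R^n +
#'   \delta_\rho (L_R^n + (R + \gamma K)^n)},}
#' with `K = pak_active_fraction(R, p)`. Decreasing in `R` (mutual
#' inhibition), contained in `(0, 1]`.
#'
#' @inheritParams pak_active_fraction
#' @return scaled active-Rho concentration.
#' @export
rho_quasi_steady <- function(R, p) {
  K <- pak_active_fraction(R, p)
  p$I_rho * p$L_R^p$n /
    (p$I_rho * p$L_R^p$n + p$delta_rho * (p$L_R^p$n + (R + p$gamma * K)^p$n))
}

#' Quasi-steady-state phosphorylated paxillin
#'
#' \deqn{P = \frac{B h}{\alpha_P B h + \delta_P}, \qquad
#'   h = \frac{K^n}{L_K^n + K^n}.}
#' `P` is zero when `K = 0` and saturates at `1 / \alpha_P` as `B`
#' grows.
#'
#' @param B maximum paxillin phosphorylation rate (`>= 0`).
#' @param K scaled active-PAK concentration (`>= 0`).
#' @param p a [kinetic_params()] object.
#' @return scaled phosphorylated-paxillin concentration.
#' @export
paxillin_quasi_steady <- function(B, K, p) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(B < 0) || any(K < 0)) stop("B and K must be nonnegative", call. = FALSE)
  if (all(B == 0) && all(K == 0) && p$delta_P == 0) {
    stop("degenerate input: B, K and delta_P all zero", call. = FALSE)
  }
  h <- K^p$n / (p$L_K^p$n + K^p$n)
  B * h / (p$alpha_P * B * h + p$delta_P)
}

# Vectorised 4V reaction terms (no diffusion); shared by the ODE and PDE paths.
# Returns dR, dB, dkB; the inactive-Rac reaction derivative is -dR.
#
# The Rac production term is proportional to the inactive pool Ri. On the
# conserved manifold Ri = 1 - R - gamma K this coincides with the
# conservation-substituted form of the two-variable reduction; keeping Ri
# explicit is what preserves total Rac mass exactly under unequal active and
# inactive diffusion, and hence supports wave-pinning.
reaction_terms_4v <- function(R, B, kB, p, Ri = NULL) {
  K <- pak_active_fraction(R, p)
  rho <- rho_quasi_steady(R, p)
  P <- paxillin_quasi_steady(B, K, p)
  Iks <- git_pix_pak_activation(P, p)
  gate <- p$L_rho^p$n / (p$L_rho^p$n + rho^p$n)
  if (is.null(Ri)) Ri <- 1 - R - p$gamma * K
  list(
    dR = (p$I_R + Iks) * gate * Ri - p$delta_R * R,
    dB = p$eps * (1 - p$gamma_R * R - kB * (B - p$B_r) +
                    1 / (p$eta * (B + p$eps_B))),
    dkB = p$eps_L * (p$gamma_K - R)
  )
}

#' Reaction part of the four-variable model
#'
#' Time derivatives of `(R, R_i, B, k_B)` under the three-timescale model:
#' fast Rac activation gated by quasi-steady Rho and fed back through
#' quasi-steady paxillin phosphorylation, a slow maximum phosphorylation rate
#' `B` relaxing towards its resting state `B_r` with a `1/(eta (B + eps_B))`
#' barrier that keeps `B` positive, and a very slow recovery rate `k_B`
#' integrating the deviation of Rac from `gamma_K`. The reaction part
#' conserves `R + R_i` exactly.
#'
#' @param state named numeric vector with entries `R`, `Ri`, `B`, `kB`.
#' @param p a [kinetic_params()] object.
#' @return named numeric vector of derivatives `(R, Ri, B, kB)`.
#' @export
rhs_4v <- function(state, p) {
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  if (state[["B"]] <= 0) {
    stop("state violation: B must be positive (got ", state[["B"]], ")",
         call. = FALSE)
  }
  d <- reaction_terms_4v(state[["R"]], state[["B"]], state[["kB"]], p,
                         Ri = state[["Ri"]])
  c(R = d$dR, Ri = -d$dR, B = d$dB, kB = d$dkB)
}

# Vectorised 6V reaction terms; each active/inactive pair is antisymmetric.
reaction_terms_6v <- function(R, Ri, rho, rhoi, P, Pi, p) {
  K <- pak_active_fraction(R, p)
  Iks <- git_pix_pak_activation(P, p)
  fR <- (p$I_R + Iks) * (p$L_rho^p$n / (p$L_rho^p$n + rho^p$n)) * Ri -
    p$delta_R * R
  frho <- p$I_rho * (p$L_R^p$n / (p$L_R^p$n + (R + p$gamma * K)^p$n)) * rhoi -
    p$delta_rho * rho
  fP <- p$B * (K^p$n / (p$L_K^p$n + K^p$n)) * Pi - p$delta_P * P
  list(dR = fR, dRi = -fR, drho = frho, drhoi = -frho, dP = fP, dPi = -fP)
}

#' Reaction part of the six-variable model
#'
#' Time derivatives of the full Rac/Rho/paxillin system in active and
#' inactive (phosphorylated and unphosphorylated) forms. Each pair's
#' derivatives sum to zero, so pair totals are conserved in the absence of
#' diffusion.
#'
#' @param state named numeric vector with entries `R`, `Ri`, `rho`, `rhoi`,
#'   `P`, `Pi`.
#' @param p a [kinetic_params()] object.
#' @return named numeric vector of the six derivatives.
#' @export
rhs_6v <- function(state, p) {
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  d <- reaction_terms_6v(state[["R"]], state[["Ri"]], state[["rho"]],
                         state[["rhoi"]], state[["P"]], state[["Pi"]], p)
  c(R = d$dR, Ri = d$dRi, rho = d$drho, rhoi = d$drhoi, P = d$dP, Pi = d$dPi)
}

#' Steady states of the two-variable reduction
#'
#' Roots of the scalar steady-state equation for active Rac at a fixed
#' maximum phosphorylation rate `B`, using the conservation
#' `R_i = 1 - R - gamma K`. Between one and three roots exist; with three,
#' the outer two are the stable low- and high-Rac states of the bistable
#' switch.
#'
#' @param p a [kinetic_params()] object.
#' @param B maximum paxillin phosphorylation rate; default `p$B`.
#' @param n_grid resolution of the root bracketing grid.
#' @return numeric vector of steady-state `R` values, increasing.
#' @export
rac_steady_states <- function(p, B = p$B, n_grid = 2000) {
  f <- function(R) {
    d <- reaction_terms_4v(R, B, 0, p)
    d$dR
  }
  Rg <- seq(1e-9, 0.9999, length.out = n_grid)
  fv <- f(Rg)
  idx <- which(diff(sign(fv)) != 0)
  vapply(idx, function(i) {
    stats::uniroot(f, c(Rg[i], Rg[i + 1]), tol = 1e-12)$root
  }, numeric(1))
}

# midpoint of the B-range over which the fast subsystem is bistable
# (three steady states); falls back to the packaged default B when the
# system is monostable everywhere on the probed range
bistable_mid_B <- function(p, B_range = c(0.2, 15), n_grid = 120) {
  Bs <- exp(seq(log(B_range[1]), log(B_range[2]), length.out = n_grid))
  tri <- vapply(Bs, function(B) length(rac_steady_states(p, B = B, n_grid = 600)) >= 3,
                logical(1))
  if (!any(tri)) return(p$B)
  (min(Bs[tri]) + max(Bs[tri])) / 2
}

#' Integrate the non-spatial kinetics
#'
#' Integrates the 4V, 2V or 6V reaction system (no diffusion) with a stiff
#' adaptive implicit integrator. The multi-timescale structure of the 4V
#' model makes the small-amplitude loops of mixed-mode oscillations
#' tolerance-sensitive, so tight defaults (`rtol = 1e-8`, `atol = 1e-10`)
#' are used.
#'
#' The default initial condition places `(R, R_i)` at the low-Rac steady
#' state of the 2V reduction (evaluated at the packaged default `B`), with
#' `B = B_r` and `k_B = 0` for the 4V model.
#'
#' @param p a [kinetic_params()] object.
#' @param t_end integration horizon (time units of the rate constants).
#' @param model one of `"4v"`, `"2v"`, `"6v"`.
#' @param init optional named initial state; defaults as described.
#' @param dt_out output sampling interval.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return a `racpax_trajectory`: list with `times`, `states` (matrix, one
#'   column per variable), `model`, `params` and solver settings.
#' @export
integrate_ode <- function(p, t_end, model = c("4v", "2v", "6v"), init = NULL,
                          dt_out = 2, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "kinetic_params"))
  model <- match.arg(model)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (is.null(init)) init <- default_init(p, model)
  times <- seq(0, t_end, by = dt_out)
  rhs <- switch(model,
    "4v" = function(t, y, parms) {
      d <- reaction_terms_4v(y[1], y[3], y[4], parms, Ri = y[2])
      list(c(d$dR, -d$dR, d$dB, d$dkB))
    },
    "2v" = function(t, y, parms) {
      d <- reaction_terms_4v(y[1], parms$B, 0, parms, Ri = y[2])
      list(c(d$dR, -d$dR))
    },
    "6v" = function(t, y, parms) {
      d <- reaction_terms_6v(y[1], y[2], y[3], y[4], y[5], y[6], parms)
      list(c(d$dR, d$dRi, d$drho, d$drhoi, d$dP, d$dPi))
    }
  )
  out <- deSolve::ode(y = init, times = times, func = rhs, parms = p,
                      method = "bdf", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("ODE integration failed (istate = ", attr(out, "istate")[1], ")",
         call. = FALSE)
  }
  states <- unclass(out)[, -1, drop = FALSE]
  if (any(!is.finite(states))) stop("non-finite values in trajectory", call. = FALSE)
  structure(
    list(times = out[, 1], states = states, model = model, params = p,
         rtol = rtol, atol = atol),
    class = "racpax_trajectory"
  )
}

default_init <- function(p, model) {
  ss <- rac_steady_states(p, B = p$B)
  Rlow <- min(ss)
  Klow <- pak_active_fraction(Rlow, p)
  Ri <- max(1 - Rlow - p$gamma * Klow, 0)
  switch(model,
    "4v" = c(R = Rlow, Ri = Ri, B = p$B_r, kB = 0),
    "2v" = c(R = Rlow, Ri = Ri),
    "6v" = c(R = Rlow, Ri = Ri,
             rho = rho_quasi_steady(Rlow, p),
             rhoi = 1 - rho_quasi_steady(Rlow, p),
             P = paxillin_quasi_steady(p$B, Klow, p),
             Pi = 1 - paxillin_quasi_steady(p$B, Klow, p))
  )
}

#' @export
print.racpax_trajectory <- function(x, ...) {
  cat(sprintf("%s-model trajectory: %d samples on [0, %g]\n",
              toupper(x$model), length(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.racpax_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

local_maxima <- function(x) which(diff(sign(diff(x))) == -2) + 1
local_minima <- function(x) which(diff(sign(diff(x))) == 2) + 1

#' Classify the oscillatory regime of a Rac trajectory
#'
#' Labels a (post-transient) trajectory of active Rac as `steady`, `RO`
#' (relaxation oscillations: one amplitude class of peaks) or `MMO`
#' (mixed-mode oscillations: small-amplitude peaks interleaved with
#' large-amplitude ones within a cycle). Peak heights are split by a
#' two-means clustering; the split is accepted as two genuine amplitude
#' classes when the cluster-centre gap is at least `split_ratio` times the
#' within-cluster spread and a non-negligible fraction (`min_gap_frac`) of
#' the signal amplitude.
#'
#' @param traj a `racpax_trajectory` (or any list with `times` and `states`
#'   containing an `R` column).
#' @param transient_frac fraction of the window discarded as burn-in.
#' @param steady_eps amplitude (scaled-concentration units) below which the
#'   post-transient signal is called steady.
#' @param split_ratio required ratio of between-cluster gap to within-cluster
#'   spread for an MMO call.
#' @param min_gap_frac minimum cluster gap as a fraction of signal amplitude.
#' @param min_cycles minimum number of cycles (peaks) required.
#' @return a `regime_label`: list with `label`, `n_small`, `n_large`,
#'   `amplitude` and peak statistics.
#' @export
classify_regime <- function(traj, transient_frac = 0.2, steady_eps = 1e-3,
                            split_ratio = 3, min_gap_frac = 0.2,
                            min_cycles = 3) {
  R <- traj$states[, "R"]
  t <- traj$times
  keep <- t >= (min(t) + transient_frac * (max(t) - min(t)))
  R <- R[keep]; t <- t[keep]
  if (length(R) < 10) stop("insufficient data for regime classification", call. = FALSE)
  amp <- diff(range(R))
  lab <- function(label, n_small = 0L, n_large = 0L, heights = numeric()) {
    structure(list(label = label, n_small = n_small, n_large = n_large,
                   amplitude = amp, peak_heights = heights),
              class = "regime_label")
  }
  pk <- local_maxima(R)
  if (amp < steady_eps || length(pk) == 0) return(lab("steady"))
  # amplitude over the final tenth of the window: a trajectory still ringing
  # down to equilibrium has few peaks and a shrinking tail, and is steady
  tail_amp <- diff(range(R[t >= max(t) - 0.1 * (max(t) - min(t))]))
  if (length(pk) < min_cycles) {
    if (tail_amp < steady_eps || tail_amp < 0.25 * amp) return(lab("steady"))
    stop("trajectory too short: only ", length(pk),
         " peaks after transient (need >= ", min_cycles, ")", call. = FALSE)
  }
  if (tail_amp < steady_eps) return(lab("steady"))
  h <- R[pk]
  if (diff(range(h)) < .Machine$double.eps^0.5 * max(1, max(abs(h)))) {
    return(lab("RO", n_large = length(h), heights = h))
  }
  km <- suppressWarnings(stats::kmeans(h, centers = range(h)))
  lo_cl <- which.min(km$centers)
  gap <- abs(diff(range(km$centers)))
  spread <- max(vapply(seq_len(2), function(k) {
    hh <- h[km$cluster == k]
    if (length(hh) < 2) 0 else diff(range(hh))
  }, numeric(1)))
  two_classes <- gap >= split_ratio * max(spread, 1e-12) && gap >= min_gap_frac * amp
  if (!two_classes) return(lab("RO", n_large = length(h), heights = h))
  small <- km$cluster == lo_cl
  # require interleaving: at least one small peak between consecutive large peaks
  big_idx <- which(!small)
  interleaved <- length(big_idx) >= 2 &&
    any(vapply(seq_len(length(big_idx) - 1), function(i) {
      any(small[(big_idx[i] + 1):(big_idx[i + 1] - 1)])
    }, logical(1)))
  if (sum(small) >= 1 && (interleaved || length(big_idx) < 2)) {
    lab("MMO", n_small = sum(small), n_large = sum(!small), heights = h)
  } else {
    lab("RO", n_large = length(h), heights = h)
  }
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("regime: %s (amplitude %.4g; %d large, %d small peaks)\n",
              x$label, x$amplitude, x$n_large, x$n_small))
  invisible(x)
}

#' Scan a kinetic parameter and map oscillatory regimes
#'
#' Integrates the 4V model at each value of a parameter grid, classifies the
#' regime, and reports transition values as midpoints between adjacent grid
#' points with differing labels.
#'
#' @param p a [kinetic_params()] object (the baseline; the scanned entry is
#'   replaced at each grid value).
#' @param name parameter name, e.g. `"L_K"`.
#' @param grid sorted numeric vector of parameter values.
#' @param t_end integration horizon per grid value.
#' @param ... further arguments to [classify_regime()].
#' @return a `regime_scan`: data frame of `value` and `label`, with a
#'   `transitions` attribute (data frame `from`, `to`, `at`).
#' @export
scan_parameter <- function(p, name, grid, t_end = 80000, ...) {
  stopifnot(inherits(p, "kinetic_params"), name %in% .param_names)
  if (is.unsorted(grid)) stop("grid must be sorted increasing", call. = FALSE)
  labels <- character(length(grid))
  for (i in seq_along(grid)) {
    over <- stats::setNames(list(grid[i]), name)
    pi_ <- do.call(kinetic_params, over)
    pi_[setdiff(.param_names, name)] <- p[setdiff(.param_names, name)]
    pi_ <- validate_kinetic_params(pi_)
    traj <- tryCatch(integrate_ode(pi_, t_end = t_end),
                     error = function(e) stop("solver failure at ", name, " = ",
                                              grid[i], ": ", conditionMessage(e),
                                              call. = FALSE))
    labels[i] <- classify_regime(traj, ...)$label
  }
  ch <- which(labels[-1] != labels[-length(labels)])
  transitions <- data.frame(
    from = labels[ch], to = labels[ch + 1],
    at = (grid[ch] + grid[ch + 1]) / 2
  )
  res <- data.frame(value = grid, label = labels)
  attr(res, "transitions") <- transitions
  class(res) <- c("regime_scan", "data.frame")
  res
}

#' @export
print.regime_scan <- function(x, ...) {
  print.data.frame(x, ...)
  tr <- attr(x, "transitions")
  if (nrow(tr)) {
    cat("transitions:\n")
    for (i in seq_len(nrow(tr))) {
      cat(sprintf("  %s -> %s at %.4g\n", tr$from[i], tr$to[i], tr$at[i]))
    }
  }
  invisible(x)
}
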