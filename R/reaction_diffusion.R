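#' One-dimensional periodic reaction-diffusion field
#'
#' Builds a field on a ring of `n` sites and physical length `L`
#' (`dx = L / n`). Active and inactive Rac diffuse with distinct
#' coefficients; in the 4V model `B` and `k_B` carry no diffusion and evolve
#' as per-site ODEs; the 2V model holds `B` fixed at `p$B`.
#'
#' @param n number of grid sites (`>= 8`).
#' @param L ring length (physical units).
#' @param model one of `"2v"`, `"4v"`, `"6v"`.
#' @param p a [kinetic_params()] object (used for default initial values).
#' @param init one of `"steady"` (spatially homogeneous low-Rac steady
#'   state), `"step"` (a high-Rac arc covering `frac` of the ring), or a
#'   numeric matrix `n x n_vars` of initial values.
#' @param frac fraction of the ring at high Rac for `init = "step"`.
#' @param B0 initial maximum phosphorylation rate used to construct the
#'   initial profile (and, for the 4V model, the initial `B` field). Defaults
#'   to `p$B`, which lies inside the bistable window at default parameters;
#'   the homogeneous `"steady"` init of the 4V model instead starts from
#'   `B_r` as in [integrate_ode()].
#' @return a `field1d`: list with `x`, `dx`, `L`, `values` (matrix, columns
#'   named by variable) and `model`.
#' @export
field1d <- function(n, L = n, model = c("4v", "2v", "6v"), p = kinetic_params(),
                    init = "steady", frac = 0.3, B0 = NULL) {
  model <- match.arg(model)
  if (n < 8) stop("need at least 8 grid sites", call. = FALSE)
  vars <- switch(model,
    "2v" = c("R", "Ri"),
    "4v" = c("R", "Ri", "B", "kB"),
    "6v" = c("R", "Ri", "rho", "rhoi", "P", "Pi"))
  x <- (seq_len(n) - 0.5) * (L / n)
  if (is.matrix(init)) {
    if (nrow(init) != n || ncol(init) != length(vars)) {
      stop("init matrix must be ", n, " x ", length(vars), call. = FALSE)
    }
    vals <- init
    colnames(vals) <- vars
  } else {
    if (is.null(B0)) {
      B0 <- if (identical(init, "steady") && model == "4v") p$B_r else p$B
    }
    # profile levels always taken from the 2V steady states at the default B,
    # so the homogeneous init matches integrate_ode()'s default exactly
    ss <- rac_steady_states(p, B = p$B)
    Rlow <- min(ss); Rhigh <- max(ss)
    Rvec <- rep(Rlow, n)
    if (identical(init, "step")) {
      if (length(ss) < 2) {
        stop("step initial condition needs a bistable parameter regime",
             call. = FALSE)
      }
      arc <- seq_len(max(1, round(frac * n)))
      Rvec[arc] <- Rhigh
    } else if (!identical(init, "steady")) {
      stop("init must be \"steady\", \"step\" or a matrix", call. = FALSE)
    }
    K <- pak_active_fraction(Rvec, p)
    Rivec <- pmax(1 - Rvec - p$gamma * K, 0)
    vals <- switch(model,
      "2v" = cbind(R = Rvec, Ri = Rivec),
      "4v" = cbind(R = Rvec, Ri = Rivec, B = rep(B0, n), kB = rep(0, n)),
      "6v" = {
        rho <- rho_quasi_steady(Rvec, p)
        P <- paxillin_quasi_steady(p$B, K, p)
        cbind(R = Rvec, Ri = Rivec, rho = rho, rhoi = 1 - rho, P = P, Pi = 1 - P)
      })
  }
  structure(list(x = x, dx = L / n, L = L, values = vals, model = model),
            class = "field1d")
}

diffusion_coefs <- function(model, p) {
  switch(model,
    "2v" = c(R = p$D_R, Ri = p$D_Ri),
    "4v" = c(R = p$D_R, Ri = p$D_Ri, B = 0, kB = 0),
    "6v" = c(R = p$D_R, Ri = p$D_Ri, rho = p$D_rho, rhoi = p$D_rhoi,
             P = p$D_P, Pi = p$D_Pi))
}

# second-order central-difference Laplacian on the ring, per column
ring_laplacian <- function(v, dx) {
  (v[c(2:nrow(v), 1), , drop = FALSE] + v[c(nrow(v), 1:(nrow(v) - 1)), , drop = FALSE] -
     2 * v) / dx^2
}

field_reaction <- function(vals, model, p) {
  switch(model,
    "2v" = {
      d <- reaction_terms_4v(vals[, "R"], p$B, 0, p, Ri = vals[, "Ri"])
      cbind(R = d$dR, Ri = -d$dR)
    },
    "4v" = {
      d <- reaction_terms_4v(vals[, "R"], vals[, "B"], vals[, "kB"], p,
                             Ri = vals[, "Ri"])
      cbind(R = d$dR, Ri = -d$dR, B = d$dB, kB = d$dkB)
    },
    "6v" = {
      d <- reaction_terms_6v(vals[, "R"], vals[, "Ri"], vals[, "rho"],
                             vals[, "rhoi"], vals[, "P"], vals[, "Pi"], p)
      cbind(R = d$dR, Ri = d$dRi, rho = d$drho, rhoi = d$drhoi,
            P = d$dP, Pi = d$dPi)
    })
}

#' Advance a 1D field by one explicit time step
#'
#' Method of lines with second-order central differences on the periodic
#' ring and forward-Euler time stepping. The step size must satisfy the
#' diffusive stability constraint `dt <= dx^2 / (2 max(D))`.
#'
#' @param f a [field1d()] object.
#' @param dt time step.
#' @param p a [kinetic_params()] object.
#' @param reactions if `FALSE`, diffusion only (used for scheme validation).
#' @param scheme `"rk2"` (Heun, second order in time; default) or `"euler"`.
#' @return the advanced `field1d`.
#' @export
step_field <- function(f, dt, p, reactions = TRUE, scheme = c("rk2", "euler")) {
  stopifnot(inherits(f, "field1d"))
  scheme <- match.arg(scheme)
  D <- diffusion_coefs(f$model, p)
  if (max(D) > 0 && dt > f$dx^2 / (2 * max(D)) * (1 + 1e-12)) {
    stop(sprintf(
      "unstable configuration: dt = %g exceeds the stability limit dx^2/(2 max D) = %g",
      dt, f$dx^2 / (2 * max(D))), call. = FALSE)
  }
  rate <- function(v) {
    dv <- sweep(ring_laplacian(v, f$dx), 2, D, `*`)
    if (reactions) dv <- dv + field_reaction(v, f$model, p)
    dv
  }
  v <- f$values
  k1 <- rate(v)
  if (scheme == "euler") {
    f$values <- v + dt * k1
  } else {
    k2 <- rate(v + dt * k1)
    f$values <- v + dt / 2 * (k1 + k2)
  }
  f
}

#' Simulate a 1D reaction-diffusion field
#'
#' Repeatedly applies [step_field()] and records snapshots. The integrated
#' mass of each conserved pair (e.g. `R + Ri`) is constant up to round-off;
#' a drift beyond `mass_rel_tol` aborts with a diagnostic.
#'
#' @param f a [field1d()] object (initial condition).
#' @param t_end simulated time span.
#' @param p a [kinetic_params()] object.
#' @param dt time step; default 80% of the stability limit.
#' @param record_every record a snapshot every this many time units.
#' @param reactions passed to [step_field()].
#' @param mass_rel_tol relative drift of conserved mass tolerated.
#' @return a `field_series`: list with `times`, `snapshots` (list of value
#'   matrices), `x`, `dx`, `L`, `model`.
#' @export
simulate_field <- function(f, t_end, p, dt = NULL, record_every = NULL,
                           reactions = TRUE, mass_rel_tol = 1e-6) {
  stopifnot(inherits(f, "field1d"))
  D <- diffusion_coefs(f$model, p)
  if (is.null(dt)) {
    dt <- if (max(D) > 0) 0.8 * f$dx^2 / (2 * max(D)) else 0.1
  }
  if (is.null(record_every)) record_every = max(t_end / 100, dt)
  n_steps <- ceiling(t_end / dt)
  rec_stride <- max(1L, round(record_every / dt))
  pairs <- list(c("R", "Ri"))
  if (f$model == "6v") pairs <- c(pairs, list(c("rho", "rhoi"), c("P", "Pi")))
  mass0 <- vapply(pairs, function(pr) sum(f$values[, pr]) * f$dx, numeric(1))
  times <- 0
  snaps <- list(f$values)
  for (s in seq_len(n_steps)) {
    f <- step_field(f, dt, p, reactions = reactions)
    if (s %% rec_stride == 0 || s == n_steps) {
      times <- c(times, s * dt)
      snaps[[length(snaps) + 1]] <- f$values
    }
  }
  mass1 <- vapply(pairs, function(pr) sum(f$values[, pr]) * f$dx, numeric(1))
  drift <- max(abs(mass1 - mass0) / pmax(abs(mass0), .Machine$double.eps))
  if (drift > mass_rel_tol) {
    stop(sprintf("conserved mass drifted by %.3g (tolerance %.3g)",
                 drift, mass_rel_tol), call. = FALSE)
  }
  structure(list(times = times, snapshots = snaps, x = f$x, dx = f$dx,
                 L = f$L, model = f$model, mass_drift = drift),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("%s-model field series: %d snapshots, %d sites on a ring of length %g\n",
              toupper(x$model), length(x$times), length(x$x), x$L))
  invisible(x)
}

# positions (in x units) where the R profile crosses level th, linear
# interpolation across edges, periodic wrap included
front_positions <- function(Rv, x, dx, th) {
  n <- length(Rv)
  nxt <- c(2:n, 1)
  lo <- Rv - th
  cross <- which(lo * lo[nxt] < 0)
  pos <- vapply(cross, function(i) {
    j <- nxt[i]
    frac <- lo[i] / (lo[i] - lo[j])
    (x[i] + frac * dx) %% (n * dx)
  }, numeric(1))
  sort(pos)
}

#' Detect wave-pinning in a field series
#'
#' A series is pinned when the final active-Rac profile is heterogeneous
#' (max - min above `contrast`) and the half-maximum front positions move
#' less than `pin_tol` grid units over the last `pin_window` fraction of the
#' simulation.
#'
#' @param series a `field_series` from [simulate_field()].
#' @param pin_tol maximum tolerated front displacement (grid units).
#' @param pin_window fraction of the simulation used for the stall test.
#' @param contrast minimum max - min of the final `R` profile.
#' @return a `pinning_report`: list with `pinned`, `fronts` (list of front
#'   position vectors over the window), `plateau_high`, `plateau_low`.
#' @export
detect_wave_pinning <- function(series, pin_tol = 1, pin_window = 0.25,
                                contrast = 0.05) {
  stopifnot(inherits(series, "field_series"))
  nt <- length(series$times)
  final <- series$snapshots[[nt]][, "R"]
  hi <- max(final); lo <- min(final)
  report <- function(pinned, fronts) {
    structure(list(pinned = pinned, fronts = fronts,
                   plateau_high = hi, plateau_low = lo),
              class = "pinning_report")
  }
  if (hi - lo < contrast) return(report(FALSE, list()))
  th <- (hi + lo) / 2
  win <- which(series$times >= (1 - pin_window) * max(series$times))
  fronts <- lapply(win, function(i) {
    front_positions(series$snapshots[[i]][, "R"], series$x, series$dx, th)
  })
  nf <- vapply(fronts, length, integer(1))
  if (any(nf == 0) || length(unique(nf)) != 1) return(report(FALSE, fronts))
  ref <- fronts[[1]]
  Lr <- series$L
  move <- max(vapply(fronts, function(fp) {
    d <- abs(fp - ref)
    max(pmin(d, Lr - d))
  }, numeric(1)))
  report(move < pin_tol * series$dx, fronts)
}

#' @export
print.pinning_report <- function(x, ...) {
  cat(sprintf("wave-pinning: %s (plateaus %.3f / %.3f, %d fronts)\n",
              if (x$pinned) "pinned" else "not pinned",
              x$plateau_high, x$plateau_low,
              if (length(x$fronts)) length(x$fronts[[1]]) else 0L))
  invisible(x)
}
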