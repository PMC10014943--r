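test_that("diffusion-only stepping follows the analytic ring-mode decay", {
  p <- default_params()
  n <- 64
  x <- seq_len(n) - 0.5
  R0 <- 0.2 + 0.1 * exp(-((x - 32)^2) / 32)
  f <- field1d(n, L = n, model = "2v", p = p,
               init = cbind(R = R0, Ri = rep(0.5, n)))
  tend <- 5
  ser <- simulate_field(f, tend, p, reactions = FALSE, record_every = tend)
  fin <- ser$snapshots[[length(ser$times)]][, "R"]
  # central-difference Laplacian eigenvalues on the ring (dx = 1)
  lam <- 2 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  expected <- Re(fft(fft(R0) * exp(-p$D_R * lam * tend), inverse = TRUE)) / n
  expect_lt(max(abs(fin - expected)), 1e-4)
})

test_that("a spatially homogeneous field stays homogeneous and tracks the ODE", {
  p <- default_params()
  f <- field1d(48, L = 48, model = "4v", p = p, init = "steady")
  ser <- simulate_field(f, 400, p, record_every = 100)
  fin <- ser$snapshots[[length(ser$times)]]
  expect_lt(max(apply(fin, 2, function(v) diff(range(v)))), 1e-12)
  tr <- integrate_ode(p, 400, dt_out = 100)
  expect_lt(max(abs(fin[1, ] - tr$states[nrow(tr$states), ])), 1e-6)
})

test_that("zero diffusion decouples sites into independent kinetics", {
  p0 <- default_params(D_R = 0, D_Ri = 0)
  n <- 16
  set.seed(5)
  R0 <- runif(n, 0.05, 0.3)
  Ri0 <- 1 - R0 - p0$gamma * pak_active_fraction(R0, p0)
  f <- field1d(n, L = n, model = "4v", p = p0,
               init = cbind(R = R0, Ri = Ri0, B = rep(4, n), kB = rep(0, n)))
  ser <- simulate_field(f, 200, p0, dt = 0.02, record_every = 200)
  fin <- ser$snapshots[[length(ser$times)]]
  # site 7 evolved alone must match the field's site 7
  init1 <- c(R = R0[7], Ri = Ri0[7], B = 4, kB = 0)
  tr <- integrate_ode(p0, 200, init = init1, dt_out = 200)
  expect_lt(max(abs(fin[7, ] - tr$states[nrow(tr$states), ])), 1e-4)
})

test_that("the stability constraint on dt is enforced", {
  p <- default_params()
  f <- field1d(32, model = "2v", p = p)
  expect_error(step_field(f, dt = 1, p), "stability")
})

test_that("Rac mass is conserved through reaction and diffusion", {
  p <- default_params()
  f <- field1d(96, L = 96, model = "4v", p = p, init = "step", frac = 0.3)
  ser <- simulate_field(f, 800, p, record_every = 200)
  expect_lt(ser$mass_drift, 1e-6)
})

test_that("a step initial condition wave-pins into a stable polarized profile", {
  p <- default_params()
  f <- field1d(128, L = 128, model = "2v", p = p, init = "step", frac = 0.3)
  ser <- simulate_field(f, 6000, p, record_every = 300)
  wp <- detect_wave_pinning(ser)
  expect_true(wp$pinned)
  expect_length(wp$fronts[[1]], 2)
  expect_gt(wp$plateau_high - wp$plateau_low, 0.1)
})

test_that("homogeneous and translating profiles are not called pinned", {
  p <- default_params()
  f <- field1d(64, L = 64, model = "2v", p = p, init = "steady")
  ser <- simulate_field(f, 500, p, record_every = 100)
  expect_false(detect_wave_pinning(ser)$pinned)
  # constructed uniformly translating front (bypasses the solver entirely)
  n <- 64
  x <- seq_len(n) - 0.5
  mk_prof <- function(c0) 0.1 + 0.3 / (1 + exp(-(((x - c0 + n / 2) %% n) - n / 2) / 2))
  snaps <- lapply(seq(0, 20, by = 2), function(s) cbind(R = mk_prof(10 + s)))
  fake <- structure(list(times = seq(0, 20, by = 2), snapshots = snaps,
                         x = x, dx = 1, L = n, model = "2v"),
                    class = "field_series")
  expect_false(detect_wave_pinning(fake)$pinned)
})

test_that("doubling the spatial resolution barely moves the pinned front", {
  p <- default_params()
  run_front <- function(n) {
    f <- field1d(n, L = 96, model = "2v", p = p, init = "step", frac = 0.3)
    ser <- simulate_field(f, 3000, p, record_every = 750)
    wp <- detect_wave_pinning(ser)
    wp$fronts[[length(wp$fronts)]]
  }
  f1 <- run_front(96)
  f2 <- run_front(192)
  # front positions in physical units; coarse cell size is 1
  expect_lt(max(abs(sort(f1) - sort(f2))), 1.0)
})
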