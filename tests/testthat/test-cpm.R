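cfg_small <- function(...) {
  cpm_config(width = 40, height = 40, S_target = 50, P_target = 30,
             init_radius = 4, mcs_total = 50, mcs_per_step = 5, ...)
}

test_that("geometric Hamiltonian matches closed forms and a pixel-count oracle", {
  cfg <- cfg_small()
  l <- matrix(0L, 10, 10)
  # single-site cell: s = 1, p = 4
  l[5, 5] <- 1L
  expect_identical(cell_area(l), 1L)
  expect_identical(cell_perimeter(l), 4L)
  expect_equal(hamiltonian_geometry(l, cfg),
               cfg$lambda_P * (4 - cfg$P_target)^2 +
                 cfg$lambda_S * (1 - cfg$S_target)^2, tolerance = 1e-12)
  # at target: zero
  cfg0 <- cpm_config(width = 40, height = 40, S_target = 1, P_target = 4,
                     init_radius = 4)
  expect_identical(hamiltonian_geometry(l, cfg0), 0)
  # random blobs against the brute-force edge count
  for (s in 1:5) {
    b <- random_blob(20 + 3 * s, 15, seed = s)
    expect_identical(cell_perimeter(b), oracle_perimeter(b))
    expect_identical(cell_area(b), sum(b > 0))
  }
})

test_that("boundary walk visits each membrane site once, in contour order", {
  l <- matrix(0L, 12, 12); l[4:9, 4:9] <- 1L
  w <- boundary_walk(l)
  expect_identical(nrow(w), 20L)  # 6x6 square: 36 - 16 interior
  expect_identical(anyDuplicated(w[, 1] + 12 * w[, 2]), 0L)
  # consecutive walk sites are Moore-adjacent
  d <- pmax(abs(diff(w[, 1])), abs(diff(w[, 2])))
  expect_true(all(d <= 1))
  # C++ kernel agrees with the R reference on random blobs
  for (s in 1:5) {
    b <- random_blob(30, 15, seed = 10 + s)
    wc <- racpax:::cpm_boundary_walk_cpp(b)
    storage.mode(wc) <- "double"
    expect_identical(wc, unname(boundary_walk(b)))
  }
})

test_that("protrusion field is zero outside, nearest-membrane inside", {
  l <- matrix(0L, 9, 9); l[3:7, 3:7] <- 1L
  w <- boundary_walk(l)
  # single constant membrane value floods the interior
  act1 <- protrusion_field(l, rep(0.4, nrow(w)), w)
  expect_true(all(act1[l > 0] == 0.4))
  expect_true(all(act1[l == 0] == 0))
  # two distinct values: interior assignment equals brute-force nearest search
  vals <- ifelse(seq_len(nrow(w)) <= nrow(w) / 2, 0.1, 0.9)
  act2 <- protrusion_field(l, vals, w)
  interior <- which(l > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(interior))) {
    i <- interior[r, 1]; j <- interior[r, 2]
    d2 <- (w[, 1] - i)^2 + (w[, 2] - j)^2
    expect_identical(act2[i, j], vals[which.min(d2)])
  }
  # C++ field agrees with the R reference
  actc <- racpax:::cpm_act_field_cpp(l, vals)
  expect_equal(actc, act2, tolerance = 1e-14)
  expect_error(protrusion_field(l, c(1, 2), w), "match")
})

test_that("protrusion-energy change follows the neighbourhood geometric means", {
  cfg <- cfg_small(lambda_Act = 10)
  l <- matrix(0L, 5, 5); l[2:4, 2:4] <- 1L
  act <- matrix(0, 5, 5); act[2:4, 2:4] <- 0.5
  # uniform Act: cell-to-cell neighbourhood means equal, dH = 0 for any
  # medium target (its mean is 0 either way)
  u <- c(3, 4); v <- c(3, 5)
  expect_equal(delta_h_act(u, v, l, act, cfg), 10 * (0 - 0.5), tolerance = 1e-12)
  cfg0 <- cfg_small(lambda_Act = 0)
  expect_identical(delta_h_act(u, v, l, act, cfg0), 0)
  # hand lattice with printed Act values against exhaustive enumeration
  set.seed(2)
  act2 <- matrix(0, 5, 5)
  act2[2:4, 2:4] <- matrix(runif(9, 0.1, 1), 3, 3)
  gm <- function(site) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- site[1] + di; jj <- site[2] + dj
      if (ii < 1 || ii > 5 || jj < 1 || jj > 5) next
      if (l[ii, jj] == l[site[1], site[2]]) vals <- c(vals, act2[ii, jj])
    }
    if (l[site[1], site[2]] == 0) 0 else exp(mean(log(vals)))
  }
  expect_equal(delta_h_act(u, v, l, act2, cfg), 10 * (gm(v) - gm(u)),
               tolerance = 1e-12)
})

test_that("Metropolis acceptance follows the energy and connectivity rules", {
  cfg <- cfg_small(lambda_Act = 0, temperature = 1e-9)
  # growing towards target area is downhill and always accepted
  l <- matrix(0L, 12, 12); l[5:7, 5:7] <- 1L  # area 9, target 50
  act <- matrix(0, 12, 12)
  res <- metropolis_attempt(l, act, cfg, u = c(5, 5), v = c(4, 5), unif = 0.99)
  expect_true(res$accepted)
  expect_lt(res$dH, 0)
  # at near-zero temperature an uphill copy (shrinking) is rejected
  res2 <- metropolis_attempt(l, act, cfg, u = c(4, 5), v = c(5, 5), unif = 1e-9)
  expect_false(res2$accepted)
  # removing a bridge site would disconnect: hard rejection regardless of dH
  lb <- matrix(0L, 9, 9)
  lb[5, 3:7] <- 1L  # a 1-wide bar; middle site is a bridge
  resb <- metropolis_attempt(lb, act, cfg, u = c(4, 5), v = c(5, 5), unif = 0)
  expect_false(resb$accepted)
  expect_identical(resb$dH, Inf)
})

test_that("ring remap conserves Rac mass and keeps surviving values", {
  l1 <- matrix(0L, 12, 12); l1[4:9, 4:9] <- 1L
  w1 <- boundary_walk(l1)
  set.seed(6)
  vals <- cbind(R = runif(nrow(w1), 0.1, 0.4), Ri = runif(nrow(w1), 0.4, 0.9),
                B = runif(nrow(w1), 2, 6), kB = rnorm(nrow(w1), 0, 0.02))
  # unchanged shape: identity
  out_same <- remap_after_deformation(w1, vals, w1)
  expect_identical(out_same, vals)
  # one-site protrusion
  l2 <- l1; l2[3, 6] <- 1L
  w2 <- boundary_walk(l2)
  out <- remap_after_deformation(w1, vals, w2)
  expect_identical(nrow(out), nrow(w2))
  expect_lt(abs(sum(out[, c("R", "Ri")]) - sum(vals[, c("R", "Ri")])) /
              sum(vals[, c("R", "Ri")]), 1e-12)
  # uniform field stays uniform with identical totals
  uni <- cbind(R = rep(0.2, nrow(w1)), Ri = rep(0.7, nrow(w1)),
               B = rep(4, nrow(w1)), kB = rep(0, nrow(w1)))
  out_u <- remap_after_deformation(w1, uni, w2)
  sc <- nrow(w1) / nrow(w2)
  expect_equal(unique(round(out_u[, "R"], 12)), round(0.2 * sc, 12))
  expect_equal(sum(out_u[, c("R", "Ri")]), sum(uni[, c("R", "Ri")]),
               tolerance = 1e-12)
})

test_that("whole runs are deterministic under seed and respect invariants", {
  p <- default_params()
  cfg <- cpm_config(width = 60, height = 60, S_target = 120, P_target = 48,
                    init_radius = 6, mcs_total = 300, mcs_per_step = 10,
                    record_every = 5, seed = 42)
  out1 <- run_cpm_simulation(cfg, p)
  out2 <- run_cpm_simulation(cfg, p)
  expect_identical(out1$track$x, out2$track$x)
  expect_identical(out1$final_lattice, out2$final_lattice)
  expect_identical(out1$membrane_R, out2$membrane_R)
  out3 <- run_cpm_simulation(cpm_config(width = 60, height = 60,
                                        S_target = 120, P_target = 48,
                                        init_radius = 6, mcs_total = 300,
                                        mcs_per_step = 10, record_every = 5,
                                        seed = 43), p)
  expect_false(identical(out1$track$x, out3$track$x))
  # topology: every recorded mask is one 4-connected component
  count_components <- function(m) {
    lab <- matrix(0L, nrow(m), ncol(m)); nxt <- 0L
    for (s in which(m)) {
      i0 <- (s - 1) %% nrow(m) + 1; j0 <- (s - 1) %/% nrow(m) + 1
      if (lab[i0, j0] > 0) next
      nxt <- nxt + 1L
      q <- list(c(i0, j0)); lab[i0, j0] <- nxt
      while (length(q)) {
        cur <- q[[1]]; q <- q[-1]
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          ii <- cur[1] + d[1]; jj <- cur[2] + d[2]
          if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
              m[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt; q <- c(q, list(c(ii, jj)))
          }
        }
      }
    }
    nxt
  }
  for (mk in out1$masks) expect_identical(count_components(mk), 1L)
  # Rac concentrations on the final ring remain in the physical range
  expect_true(all(out1$final_ring[, "R"] > 0))
  expect_true(all(out1$final_ring[, "B"] > 0))
  # mean ring concentration is conserved across the whole run (fixed ring
  # length, mass = mean * L0)
  expect_equal(mean(out1$final_ring[, "R"] + out1$final_ring[, "Ri"]),
               0.9057, tolerance = 0.01)
})

test_that("without protrusion drive the track is diffusive", {
  p <- default_params()
  cfg <- cpm_config(width = 80, height = 80, S_target = 120, P_target = 48,
                    init_radius = 6, lambda_Act = 0, mcs_total = 3000,
                    mcs_per_step = 10, seed = 7)
  out <- run_cpm_simulation(cfg, p, masks = FALSE)
  a <- alpha_value(out$track)$alpha
  expect_lt(a, 1.4)  # no drive: inactive-class motion
  expect_lt(directionality_ratio(out$track), 0.5)
})
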