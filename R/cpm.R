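#' Cellular Potts simulation settings
#'
#' Hamiltonian weights and run geometry for the single-cell simulator:
#' `H = lambda_P (p - P_target)^2 + lambda_S (s - S_target)^2 + H_Act`,
#' with the protrusion term driven by membrane active Rac. Copy attempts
#' are accepted by the Metropolis rule at the given `temperature`.
#'
#' @param width,height lattice dimensions (sites). The simulation lattice
#'   is toroidal (periodic in both directions), so a migrating cell never
#'   meets a border; the recorded track is unwrapped.
#' @param lambda_P,lambda_S deformation-resistance weights (perimeter and
#'   surface area terms).
#' @param P_target,S_target target perimeter (cell-medium edge count) and
#'   area (sites).
#' @param lambda_Act protrusion weight.
#' @param temperature Metropolis acceptance scale (energy units).
#' @param mcs_total Monte Carlo steps (one boundary sweep each).
#' @param dt kinetics time advanced per MCS (model time units).
#' @param pde_substeps minimum number of explicit substeps per MCS (the
#'   actual count also respects the diffusive stability limit).
#' @param mcs_per_step recorded-track sampling: one track step spans this
#'   many MCS.
#' @param record_every store a mask snapshot every this many recorded steps.
#' @param init_radius radius of the initial disc-shaped cell.
#' @param B0 initial value of the membrane `B` field; by default the
#'   smaller of the packaged 2V default `B` and the midpoint of the
#'   bistable window of the fast subsystem, so that oscillatory regimes
#'   start below their jump threshold and break symmetry spatially rather
#'   than jumping up as a whole.
#' @param seed random seed (all lattice randomness flows from it).
#' @return a `cpm_config` list.
#' @export
cpm_config <- function(width = 150, height = 150,
                       lambda_P = 0.5, lambda_S = 1,
                       P_target = 96, S_target = 450,
                       lambda_Act = 20, temperature = 1.5,
                       mcs_total = 20000, dt = 8, pde_substeps = 1,
                       mcs_per_step = 55, record_every = 1,
                       init_radius = 12, B0 = NULL, seed = 1) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              lambda_P = lambda_P, lambda_S = lambda_S,
              P_target = P_target, S_target = S_target,
              lambda_Act = lambda_Act, temperature = temperature,
              mcs_total = as.integer(mcs_total), dt = dt,
              pde_substeps = as.integer(pde_substeps),
              mcs_per_step = as.integer(mcs_per_step),
              record_every = as.integer(record_every),
              init_radius = init_radius,
              B0 = if (is.null(B0)) NA_real_ else B0, seed = as.integer(seed))
  if (any(unlist(cfg[c("lambda_P", "lambda_S", "P_target", "S_target",
                       "lambda_Act", "temperature")]) < 0)) {
    stop("weights, targets and temperature must be nonnegative", call. = FALSE)
  }
  if (pi * init_radius^2 > 0.25 * width * height) {
    stop("lattice too small for the initial cell", call. = FALSE)
  }
  structure(cfg, class = "cpm_config")
}

#' Initial disc-shaped cell lattice
#'
#' @param cfg a [cpm_config()].
#' @return integer matrix (`width` x `height`), 0 = medium, 1 = cell.
#' @export
cpm_lattice <- function(cfg) {
  stopifnot(inherits(cfg, "cpm_config"))
  m <- matrix(0L, cfg$width, cfg$height)
  cx <- (cfg$width + 1) / 2; cy <- (cfg$height + 1) / 2
  d2 <- (row(m) - cx)^2 + (col(m) - cy)^2
  m[d2 <= cfg$init_radius^2] <- 1L
  m
}

#' Cell area (site count)
#' @param l integer lattice matrix.
#' @export
cell_area <- function(l) sum(l > 0)

#' Cell perimeter as cell-medium edge count
#'
#' The perimeter entering the Hamiltonian is the number of 4-adjacent
#' (cell, medium) site pairs; sites beyond the lattice count as medium.
#'
#' @param l integer lattice matrix.
#' @export
cell_perimeter <- function(l) {
  cell <- l > 0
  # pad with one ring of medium
  nr <- nrow(cell); nc <- ncol(cell)
  big <- matrix(FALSE, nr + 2, nc + 2)
  big[2:(nr + 1), 2:(nc + 1)] <- cell
  core <- big[2:(nr + 1), 2:(nc + 1)]
  sum(core & !big[1:nr, 2:(nc + 1)]) + sum(core & !big[3:(nr + 2), 2:(nc + 1)]) +
    sum(core & !big[2:(nr + 1), 1:nc]) + sum(core & !big[2:(nr + 1), 3:(nc + 2)])
}

#' Geometric part of the CPM Hamiltonian
#'
#' `lambda_P (p - P_target)^2 + lambda_S (s - S_target)^2`; the protrusion
#' term is handled incrementally in copy attempts.
#'
#' @param l integer lattice matrix.
#' @param cfg a [cpm_config()].
#' @export
hamiltonian_geometry <- function(l, cfg) {
  stopifnot(inherits(cfg, "cpm_config"))
  cfg$lambda_P * (cell_perimeter(l) - cfg$P_target)^2 +
    cfg$lambda_S * (cell_area(l) - cfg$S_target)^2
}

#' Ordered boundary walk of the cell membrane
#'
#' Membrane sites (cell sites with at least one medium site in their Moore
#' neighbourhood) ordered by a Moore-neighbour boundary trace starting from
#' the first cell site in column-major order; each membrane site appears
#' once, in contour order.
#'
#' @param l integer lattice matrix.
#' @return two-column matrix of (row, col) coordinates in walk order.
#' @export
boundary_walk <- function(l) {
  cell <- l > 0
  if (!any(cell)) stop("degenerate cell: no sites", call. = FALSE)
  nr <- nrow(l); nc <- ncol(l)
  at <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && cell[i, j]
  idx <- which(cell)
  start <- c((idx[1] - 1) %% nr + 1, (idx[1] - 1) %/% nr + 1)
  if (sum(cell) == 1) return(matrix(start, 1, 2))
  # Moore neighbours in cyclic order (W, NW, N, NE, E, SE, S, SW)
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  # Moore-neighbour trace with backtrack bookkeeping (Jacob's criterion):
  # search the neighbourhood of the current pixel starting just after the
  # backtrack pixel; the first cell pixel becomes current, the last medium
  # pixel checked becomes the new backtrack
  path <- list()
  cur <- start
  b <- start + moves[3, ]  # north of start is medium (first in scan order)
  b0 <- b
  guard <- 8 * nr * nc
  repeat {
    path[[length(path) + 1]] <- cur
    db <- b - cur
    kb <- which(moves[, 1] == db[1] & moves[, 2] == db[2])
    found <- FALSE
    for (k in 1:8) {
      d <- (kb - 1 + k) %% 8 + 1
      nb <- cur + moves[d, ]
      if (at(nb[1], nb[2])) {
        b <- cur + moves[(d - 2) %% 8 + 1, ]  # last medium pixel checked
        cur <- nb
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated site
    guard <- guard - 1
    if (guard <= 0) break
    if (all(cur == start) && all(b == b0) && length(path) > 1) break
  }
  pts <- do.call(rbind, path)
  # keep first occurrence of each membrane site, in order
  key <- pts[, 1] + nr * pts[, 2]
  pts <- pts[!duplicated(key), , drop = FALSE]
  # restrict to membrane sites (Moore-adjacent to medium or lattice edge)
  is_mem <- vapply(seq_len(nrow(pts)), function(r) {
    i <- pts[r, 1]; j <- pts[r, 2]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      if (!at(i + di, j + dj)) return(TRUE)
    }
    FALSE
  }, logical(1))
  pts[is_mem, , drop = FALSE]
}

#' Protrusion-energy field from membrane Rac
#'
#' Membrane sites carry their scaled active-Rac value; interior cell sites
#' take the value of their closest membrane site (Euclidean distance, ties
#' broken by lowest walk index); medium sites are zero.
#'
#' @param l integer lattice matrix.
#' @param membrane_R numeric vector of `R` values, one per walk site.
#' @param walk output of [boundary_walk()] (recomputed if `NULL`).
#' @return numeric matrix (the `Act` field).
#' @export
protrusion_field <- function(l, membrane_R, walk = NULL) {
  if (is.null(walk)) walk <- boundary_walk(l)
  if (nrow(walk) == 0) stop("degenerate cell: empty membrane", call. = FALSE)
  if (length(membrane_R) != nrow(walk)) {
    stop("membrane_R length (", length(membrane_R),
         ") must match walk length (", nrow(walk), ")", call. = FALSE)
  }
  act <- matrix(0, nrow(l), ncol(l))
  act[walk] <- membrane_R
  mem_key <- walk[, 1] + nrow(l) * walk[, 2]
  inner <- which(l > 0 & !(row(l) + nrow(l) * col(l)) %in% mem_key)
  for (s in inner) {
    i <- (s - 1) %% nrow(l) + 1; j <- (s - 1) %/% nrow(l) + 1
    d2 <- (walk[, 1] - i)^2 + (walk[, 2] - j)^2
    act[i, j] <- membrane_R[which.min(d2)]  # which.min takes lowest index on ties
  }
  act
}

# geometric mean of Act over the Moore neighbourhood (focal site included)
# restricted to sites sharing the focal site's label; medium focal sites
# score 0 (their Act is identically 0)
act_neighbourhood_mean <- function(site, l, act) {
  i <- site[1]; j <- site[2]
  lab <- l[i, j]
  if (lab == 0) return(0)
  vals <- c()
  for (di in -1:1) for (dj in -1:1) {
    ii <- i + di; jj <- j + dj
    if (ii < 1 || ii > nrow(l) || jj < 1 || jj > ncol(l)) next
    if (l[ii, jj] == lab) vals <- c(vals, act[ii, jj])
  }
  if (!length(vals)) return(0)
  if (any(vals == 0)) return(0)
  exp(mean(log(vals)))
}

#' Protrusion-energy change of a copy attempt
#'
#' For a copy from site `u` into adjacent site `v`,
#' `dH_Act = lambda_Act (GM_V(v) - GM_V(u))` where `GM` is the geometric
#' mean of the `Act` field over the Moore neighbourhood restricted to sites
#' sharing the focal site's label. Copies from active membrane into less
#' active sites lower the energy and are favoured.
#'
#' @param u,v `(row, col)` coordinates of adjacent source and target sites.
#' @param l integer lattice matrix.
#' @param act protrusion field from [protrusion_field()].
#' @param cfg a [cpm_config()].
#' @return energy change.
#' @export
delta_h_act <- function(u, v, l, act, cfg) {
  stopifnot(inherits(cfg, "cpm_config"))
  if (max(abs(u - v)) > 1) stop("u and v must be adjacent", call. = FALSE)
  cfg$lambda_Act * (act_neighbourhood_mean(v, l, act) -
                      act_neighbourhood_mean(u, l, act))
}

# would removing cell site v disconnect the cell locally? cell sites in the
# Moore neighbourhood of v must stay 4-connected within that neighbourhood
locally_connected_without <- function(v, l) {
  i <- v[1]; j <- v[2]
  nb <- list()
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ii <- i + di; jj <- j + dj
    if (ii >= 1 && ii <= nrow(l) && jj >= 1 && jj <= ncol(l) && l[ii, jj] > 0) {
      nb[[length(nb) + 1]] <- c(di, dj)
    }
  }
  if (!length(nb)) return(FALSE)
  # BFS over neighbour offsets with 4-adjacency inside the 3x3 window
  seen <- rep(FALSE, length(nb))
  # seed from a 4-neighbour of v if one exists (diagonal-only contact is
  # not 4-connectivity to the rest through this neighbourhood)
  seed <- which(vapply(nb, function(d) sum(abs(d)) == 1, logical(1)))[1]
  if (is.na(seed)) return(FALSE)
  queue <- seed; seen[seed] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (k in seq_along(nb)) {
      if (!seen[k] && sum(abs(nb[[cur]] - nb[[k]])) == 1) {
        seen[k] <- TRUE; queue <- c(queue, k)
      }
    }
  }
  all(seen)
}

#' Single Metropolis copy attempt
#'
#' Proposes copying the label of `u` into the adjacent site `v`, computes
#' `dH = dH_geometry + dH_Act`, and accepts with probability
#' `min(1, exp(-dH / temperature))`. Copies that would disconnect the cell,
#' empty it, or push it onto the lattice border are rejected outright.
#'
#' @param l integer lattice matrix.
#' @param act protrusion field.
#' @param cfg a [cpm_config()].
#' @param u,v source and target sites (`(row, col)`, adjacent, different
#'   labels).
#' @param unif a uniform random number in `[0,1)` (supplied so that callers
#'   control the random stream).
#' @return list with `accepted`, `lattice`, `dH`.
#' @export
metropolis_attempt <- function(l, act, cfg, u, v, unif = stats::runif(1)) {
  stopifnot(inherits(cfg, "cpm_config"))
  if (l[u[1], u[2]] == l[v[1], v[2]]) {
    stop("u and v must carry different labels", call. = FALSE)
  }
  gaining <- l[u[1], u[2]] > 0  # cell grows into v
  if (!gaining) {
    if (cell_area(l) <= 1) return(list(accepted = FALSE, lattice = l, dH = Inf))
    if (!locally_connected_without(v, l)) {
      return(list(accepted = FALSE, lattice = l, dH = Inf))
    }
  } else {
    if (v[1] <= 1 || v[1] >= nrow(l) || v[2] <= 1 || v[2] >= ncol(l)) {
      return(list(accepted = FALSE, lattice = l, dH = Inf, border = TRUE))
    }
  }
  p0 <- cell_perimeter(l); s0 <- cell_area(l)
  l2 <- l
  l2[v[1], v[2]] <- l[u[1], u[2]]
  p1 <- cell_perimeter(l2); s1 <- cell_area(l2)
  dH_geom <- cfg$lambda_P * ((p1 - cfg$P_target)^2 - (p0 - cfg$P_target)^2) +
    cfg$lambda_S * ((s1 - cfg$S_target)^2 - (s0 - cfg$S_target)^2)
  dH <- dH_geom + delta_h_act(u, v, l, act, cfg)
  acc <- dH <= 0 || unif < exp(-dH / cfg$temperature)
  list(accepted = acc, lattice = if (acc) l2 else l, dH = dH)
}

#' Map a 1D kinetics field onto the membrane and back
#'
#' The membrane ring grid has one site per membrane lattice site (`dx` = 1
#' lattice unit), mapped one-to-one in boundary-walk order, so the mapping
#' for an unchanged shape is the identity.
#'
#' After a deformation, values are carried to the surviving membrane sites;
#' sites gained by the new membrane take the walk-order interpolation (mean
#' of the nearest surviving sites on either side along the new walk); the
#' `R` and `Ri` columns are then multiplicatively renormalized so the total
#' Rac mass (active + inactive) is exactly preserved.
#'
#' @param old_walk,new_walk boundary walks (two-column coordinate matrices).
#' @param old_vals numeric matrix, one row per old walk site, columns
#'   (`R`, `Ri`, `B`, `kB`).
#' @return numeric matrix with one row per new walk site.
#' @export
remap_after_deformation <- function(old_walk, old_vals, new_walk) {
  if (nrow(old_walk) != nrow(old_vals)) stop("walk/value size mismatch", call. = FALSE)
  m <- nrow(new_walk)
  old_key <- old_walk[, 1] + 1e6 * old_walk[, 2]
  new_key <- new_walk[, 1] + 1e6 * new_walk[, 2]
  pos <- match(new_key, old_key)
  out <- matrix(NA_real_, m, ncol(old_vals))
  colnames(out) <- colnames(old_vals)
  surv <- which(!is.na(pos))
  out[surv, ] <- old_vals[pos[surv], , drop = FALSE]
  if (!length(surv)) stop("topology error: no surviving membrane sites", call. = FALSE)
  gained <- setdiff(seq_len(m), surv)
  for (g in gained) {
    # nearest surviving positions along the ring in both directions
    dfwd <- (surv - g) %% m; dbwd <- (g - surv) %% m
    nxt <- surv[which.min(dfwd)]
    prv <- surv[which.min(dbwd)]
    out[g, ] <- (out[nxt, ] + out[prv, ]) / 2
  }
  mass_old <- sum(old_vals[, "R"]) + sum(old_vals[, "Ri"])
  mass_new <- sum(out[, "R"]) + sum(out[, "Ri"])
  if (mass_new > 0) {
    fac <- mass_old / mass_new
    out[, "R"] <- out[, "R"] * fac
    out[, "Ri"] <- out[, "Ri"] * fac
  }
  out
}

#' @rdname remap_after_deformation
#' @param f a [field1d()] object whose ring length equals the walk length.
#' @param walk the current boundary walk.
#' @return for `map_pde_to_perimeter()`: the membrane `R` vector.
#' @export
map_pde_to_perimeter <- function(f, walk) {
  stopifnot(inherits(f, "field1d"))
  if (length(f$x) != nrow(walk)) {
    stop("ring length (", length(f$x), ") must equal membrane size (",
         nrow(walk), ")", call. = FALSE)
  }
  f$values[, "R"]
}

#' Run the coupled Cellular Potts / membrane-kinetics simulation
#'
#' Per MCS the 4V kinetics advance on the membrane ring (reaction plus
#' diffusion of `R` and `Ri` along the membrane), the protrusion field is
#' rebuilt from membrane Rac, one sweep of Metropolis copy attempts runs,
#' and the ring is remapped onto the deformed membrane with exact Rac mass
#' conservation. The centroid is recorded every `mcs_per_step` MCS as one
#' track step; masks are stored every `record_every` recorded steps.
#'
#' @param cfg a [cpm_config()].
#' @param p a [kinetic_params()] object.
#' @param masks record mask snapshots (memory-heavy for long runs).
#' @return a `cpm_output`: list with `track` (a [track()]), `masks`,
#'   `membrane_R` (mean membrane Rac per MCS), `accepted` (accepted copies
#'   per MCS), `final_lattice`, `final_ring`, `config`, `seed`, `aborted`.
#' @export
run_cpm_simulation <- function(cfg, p = kinetic_params(), masks = TRUE) {
  stopifnot(inherits(cfg, "cpm_config"), inherits(p, "kinetic_params"))
  l <- cpm_lattice(cfg)
  if (is.na(cfg$B0)) cfg$B0 <- min(p$B, bistable_mid_B(p))
  ss <- rac_steady_states(p, B = cfg$B0)
  Rlow <- min(ss); Rhigh <- max(ss)
  Ri0 <- 1 - Rlow - p$gamma * pak_active_fraction(Rlow, p)
  # conserved per-site Rac total: the value the low steady state carries
  targetC <- Rlow + Ri0
  res <- cpm_run_cpp(l, unclass(cfg), unclass(p), Rlow, Rhigh, targetC,
                     as.logical(masks))
  steps <- seq_len(nrow(res$track)) - 1
  out <- list(
    track = track(steps, res$track[, 1], res$track[, 2], source = "cpm"),
    masks = res$masks,
    membrane_R = res$mean_R,
    accepted = res$accepted,
    final_lattice = res$lattice,
    final_ring = res$ring,
    config = cfg, seed = cfg$seed, aborted = res$aborted
  )
  if (res$aborted) {
    warning("run aborted at MCS ", res$abort_mcs,
            ": cell became degenerate")
  }
  class(out) <- "cpm_output"
  out
}

#' @export
print.cpm_output <- function(x, ...) {
  cat(sprintf("CPM run: %d track steps, %d masks, seed %d%s\n",
              nrow(x$track), length(x$masks), x$seed,
              if (x$aborted) " (ABORTED)" else ""))
  invisible(x)
}
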