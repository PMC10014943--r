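# shared fixtures: small parameter sets and an independent high-precision
# evaluation of the closed-form kinetic expressions (the oracle path keeps
# every formula written out longhand, independent of the package internals)

default_params <- function(...) kinetic_params(...)

# longhand evaluation of K, I_K*, rho_qss, P_qss for scalar inputs
oracle_K <- function(R, p) {
  num <- p$alpha_R * R
  den <- (1 + p$k_X * p$PIX) * (1 + p$alpha_R * R) +
    (p$k_G * p$k_X * p$GIT * p$PIX) / (1 + p$k_X * p$PIX + 3 / (1 + R))
  num / den
}
oracle_IKstar <- function(P, p) {
  p$I_K * (1 - 1 / (1.5 + p$k_X * p$PIX +
    p$k_G * p$k_X * p$k_C * p$GIT * p$PIX * p$Pax_tot * P))
}
oracle_rho <- function(R, p) {
  K <- oracle_K(R, p)
  a <- p$I_rho * p$L_R^p$n
  a / (a + p$delta_rho * (p$L_R^p$n + (R + p$gamma * K)^p$n))
}
oracle_P <- function(B, K, p) {
  h <- K^p$n / (p$L_K^p$n + K^p$n)
  B * h / (p$alpha_P * B * h + p$delta_P)
}

# brute-force perimeter: loop over sites and 4-neighbours
oracle_perimeter <- function(l) {
  per <- 0L
  nr <- nrow(l); nc <- ncol(l)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (l[i, j] > 0) {
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || l[ii, jj] == 0) per <- per + 1L
      }
    }
  }
  per
}

# a small random blob lattice (connected, via random walk growth)
random_blob <- function(n_sites = 25, dim = 15, seed = 1) {
  set.seed(seed)
  l <- matrix(0L, dim, dim)
  cur <- c(ceiling(dim / 2), ceiling(dim / 2))
  l[cur[1], cur[2]] <- 1L
  while (sum(l) < n_sites) {
    cells <- which(l > 0, arr.ind = TRUE)
    src <- cells[sample(nrow(cells), 1), ]
    d <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[[sample(4, 1)]]
    nb <- src + d
    if (all(nb >= 2) && all(nb <= dim - 1)) l[nb[1], nb[2]] <- 1L
  }
  l
}
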