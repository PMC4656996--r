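# shared tiny constructors for the test suite

ca_beads <- function(n, charge = 0, domain = "NTD") {
  data.frame(chain = 1L, resid = seq_len(n), kind = "CA", name = "A",
             charge = charge, domain = domain, subunit = 1L)
}

# gently bent open chain, spacing ~3.8 A
chain_coords <- function(n) {
  cbind(3.8 * (seq_len(n) - 1), 0.5 * sin(seq_len(n)), 0.3 * cos(seq_len(n)))
}

# two beads joined by one harmonic bond U = kf (r - r0)^2
harmonic_dimer <- function(kf = 0.5, r0 = 50, ff = default_forcefield()) {
  topo <- cg_topology(ca_beads(2),
                      bonds = data.frame(i = 1L, j = 2L, kf = kf, r0 = r0,
                                         cat = "disordered"))
  list(topo = topo, sys = build_sim_system(topo, ff),
       coords = rbind(c(0, 0, 0), c(r0 + 1, 0, 0)))
}

# finite-difference force check: max relative error over all coordinates
fd_force_error <- function(sys, x, h = 1e-5, idx = NULL) {
  e <- total_energy(sys, x, forces = TRUE)
  if (is.null(idx))
    idx <- cbind(rep(seq_len(nrow(x)), each = 3), rep(1:3, nrow(x)))
  err <- 0
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; d <- idx[r, 2]
    xp <- x; xm <- x
    xp[i, d] <- xp[i, d] + h; xm[i, d] <- xm[i, d] - h
    fd <- -(total_energy(sys, xp)$total - total_energy(sys, xm)$total) /
      (2 * h)
    err <- max(err, abs(fd - e$forces[i, d]) / max(1, abs(e$forces[i, d])))
  }
  err
}

# expand c*(x-a)^2*(x-b)^2 into polynomial coefficients (constant first)
double_well_coef <- function(a = 8, b = 20, c = 0.00154) {
  p1 <- c(a * b, -(a + b), 1)
  out <- rep(0, 5)
  for (i in 1:3) for (j in 1:3) out[i + j - 1] <- out[i + j - 1] + p1[i] * p1[j]
  c * out
}

kB <- 0.0019872041

# exact per-bin free energy of the double well: F = -kT ln integral of the
# Boltzmann weight over each bin (WHAM estimates bin probabilities, so the
# reference must be bin-integrated, not point-evaluated)
double_well_bin_F <- function(breaks, a = 8, b = 20, c = 0.00154,
                              temperature = 300) {
  kT <- kB * temperature
  U <- function(x) c * (x - a)^2 * (x - b)^2
  lo <- head(breaks, -1); hi <- tail(breaks, -1)
  p <- mapply(function(l, h)
    integrate(function(x) exp(-U(x) / kT), l, h)$value, lo, hi)
  -kT * log(p)
}
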