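test_that("a free bead with zero velocity and no noise stays put", {
  ff <- default_forcefield()
  topo <- cg_topology(ca_beads(1))
  sys <- build_sim_system(topo, ff)
  st <- sim_state(matrix(c(1, 2, 3), 1, 3))
  lp <- langevin_params(dt = 0.1, gamma = 0, temperature = 300, seed = 1)
  out <- langevin_step(st, sys, lp, 500)
  expect_identical(out$coords, st$coords)
  expect_identical(out$velocities, st$velocities)
})

test_that("NVE limit: energy drift < 1e-4 kcal/mol per 1e5 steps", {
  dimer <- harmonic_dimer(kf = 0.5, r0 = 50)
  st <- sim_state(dimer$coords,
                  matrix(c(0, 0, 0, 0.05, 0.02, 0), 2, 3, byrow = TRUE))
  lp <- langevin_params(dt = 0.1, gamma = 0, temperature = 300, seed = 7)
  traj <- run_simulation(dimer$sys, st, lp, 1e5, stride = 1000)
  E <- traj$energies$total + 1.5 * 2 * kB * traj$energies$kin_temperature
  expect_lt(abs(E[length(E)] - E[1]), 1e-4)
  expect_lt(diff(range(E)), 1e-4)
})

test_that("equipartition: positional variance of a harmonic dimer", {
  # U = (1/2) k (r - r0)^2 with k = 1 kcal/mol/A^2 -> <(r-r0)^2> = kB T / k
  dimer <- harmonic_dimer(kf = 0.5, r0 = 50)
  lp <- langevin_params(dt = 0.1, gamma = 0.02, temperature = 300, seed = 11)
  traj <- run_simulation(dimer$sys, sim_state(dimer$coords), lp, 1e7,
                         stride = 100)
  r <- sqrt(colSums((traj$frames[1, , ] - traj$frames[2, , ])^2))
  v <- mean((r[-(1:5000)] - 50)^2)
  expect_equal(v, kB * 300, tolerance = 0.02)
})

test_that("thermostat holds the kinetic temperature within 1%", {
  ff <- default_forcefield()
  fx <- make_toy_fixture("free_dna", params = list(dna_bp = 30))
  sys <- build_sim_system(fx$topology, ff)
  lp <- langevin_params(dt = 0.05, gamma = 0.5, temperature = 300, seed = 3)
  traj <- run_simulation(sys, fx$coords, lp, 6e4, stride = 50)
  Tk <- mean(traj$energies$kin_temperature[-(1:200)])
  expect_equal(Tk, 300, tolerance = 0.01)
})

test_that("same seed gives a bitwise identical trajectory", {
  dimer <- harmonic_dimer()
  lp <- langevin_params(dt = 0.1, gamma = 0.02, temperature = 300, seed = 5)
  a <- run_simulation(dimer$sys, sim_state(dimer$coords), lp, 2000,
                      stride = 100)
  b <- run_simulation(dimer$sys, sim_state(dimer$coords), lp, 2000,
                      stride = 100)
  expect_identical(a$frames, b$frames)
  lp2 <- langevin_params(dt = 0.1, gamma = 0.02, temperature = 300,
                         seed = 6)
  c2 <- run_simulation(dimer$sys, sim_state(dimer$coords), lp2, 2000,
                       stride = 100)
  expect_false(identical(a$frames, c2$frames))
})

test_that("checkpoint restart reproduces the continuation bitwise", {
  dimer <- harmonic_dimer()
  lp <- langevin_params(dt = 0.1, gamma = 0.02, temperature = 300, seed = 9)
  full <- run_simulation(dimer$sys, sim_state(dimer$coords), lp, 4000,
                         stride = 200)
  half <- run_simulation(dimer$sys, sim_state(dimer$coords), lp, 2000,
                         stride = 200)
  ckpt <- tempfile()
  write_checkpoint(half$state, ckpt, seed = 9)
  st <- read_checkpoint(ckpt)
  expect_equal(attr(st, "seed"), 9)
  resumed <- run_simulation(dimer$sys, st, lp, 2000, stride = 200)
  expect_equal(resumed$frames[, , 10], full$frames[, , 20],
               tolerance = 1e-12)
  # in-memory restart is exactly bitwise
  resumed2 <- run_simulation(dimer$sys, half$state, lp, 2000, stride = 200)
  expect_identical(resumed2$frames[, , 10], full$frames[, , 20])
})

test_that("fixed beads never move and keep zero velocity", {
  ff <- default_forcefield()
  fx <- fix_dna_ends(make_toy_fixture("free_dna", params = list(dna_bp = 30)))
  sys <- build_sim_system(fx$topology, ff)
  lp <- langevin_params(dt = 0.1, gamma = 0.02, temperature = 300, seed = 2)
  traj <- run_simulation(sys, fx$coords, lp, 20000, stride = 1000)
  fixed <- which(fx$topology$fixed)
  expect_gt(length(fixed), 0)
  for (f in seq_len(dim(traj$frames)[3]))
    expect_identical(traj$frames[fixed, , f], fx$coords[fixed, ])
  expect_true(all(traj$state$velocities[fixed, ] == 0))
  # free beads did move
  free <- which(!fx$topology$fixed)
  expect_gt(max(abs(traj$state$coords[free, ] - fx$coords[free, ])), 0.1)
})

test_that("zero-step run returns the input coordinates", {
  dimer <- harmonic_dimer()
  lp <- langevin_params()
  traj <- run_simulation(dimer$sys, sim_state(dimer$coords), lp, 0)
  expect_equal(dim(traj$frames)[3], 1)
  expect_identical(traj$frames[, , 1], dimer$coords)
})

test_that("the spherical container confines a hot free chain", {
  ff <- default_forcefield()
  dm <- domain_map("NTD", 1, 8, folded = FALSE)
  topo <- build_protein_topology("KAKAKAKA", dm, ff = ff)
  sys <- build_sim_system(topo, ff,
                          container = list(center = c(0, 0, 0), radius = 30,
                                           k = 10))
  lp <- langevin_params(dt = 0.05, gamma = 0.1, temperature = 600, seed = 4)
  traj <- run_simulation(sys, topo$coords, lp, 2e5, stride = 200)
  cent <- apply(traj$frames, 3, function(fr) sqrt(sum(colMeans(fr)^2)))
  expect_lt(max(cent), 30 + 5)
  # the chain actually explores the container
  expect_gt(max(cent), 5)
})

test_that("naked duplex under Langevin stays near-straight but fluctuates", {
  ff <- default_forcefield()
  fx <- fix_dna_ends(make_toy_fixture("free_dna", params = list(dna_bp = 30)))
  sys <- build_sim_system(fx$topology, ff)
  lp <- langevin_params(dt = 0.1, gamma = 0.05, temperature = 300, seed = 6)
  traj <- run_simulation(sys, fx$coords, lp, 1.5e5, stride = 1500)
  prof <- bend_score(traj, fx$topology, w = 10)
  expect_true(all(prof$score < 1))       # thermal bending lowers the score
  expect_true(all(prof$score > 0.8))     # but the duplex stays stiff
  expect_lt(sd(prof$score), 0.05)        # roughly flat profile
})
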