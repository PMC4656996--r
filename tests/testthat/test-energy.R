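test_that("Go 12-10 contact energy has the analytic minimum and tail", {
  expect_equal(contact_energy(1, 1, 1), -1)
  expect_equal(contact_energy(7.3, 7.3, 0.42), -0.42)
  expect_equal(contact_energy(2, 1, 1), 5 * 2^-12 - 6 * 2^-10)
  # stationary at r0 (finite differences)
  h <- 1e-6
  expect_lt(abs(contact_energy(1 + h, 1, 1) - contact_energy(1 - h, 1, 1)) /
              (2 * h), 1e-6)
  # decays to zero
  expect_lt(abs(contact_energy(500, 5, 1)), 1e-12)
})

test_that("Debye-Hueckel energy matches the closed form and screening", {
  expect_equal(debye_huckel_energy(10, 0, 1), 0)
  expect_equal(debye_length(300, 0.21, 78), 6.6376, tolerance = 1e-4)
  # functional identity U(2r)/U(r) = 1/2 exp(-r/lambda)
  lam <- debye_length(300, 0.21, 78)
  for (r in c(4, 9, 17)) {
    expect_equal(debye_huckel_energy(2 * r, 1, 1) /
                   debye_huckel_energy(r, 1, 1),
                 0.5 * exp(-r / lam), tolerance = 1e-12)
  }
})

test_that("Debye screening: ln|U| + ln r is linear with slope -1/lambda", {
  r <- seq(5, 40, by = 0.5)
  u <- debye_huckel_energy(r, 1, -1)
  fit <- lm(I(log(abs(u)) + log(r)) ~ r)
  lam_fit <- -1 / coef(fit)[["r"]]
  expect_gt(suppressWarnings(summary(fit)$r.squared), 0.999999)
  expect_equal(lam_fit, debye_length(300, 0.21, 78), tolerance = 1e-6)
})

test_that("excluded volume is truncated-shifted and monotone", {
  expect_equal(excluded_volume_energy(4, 4, 0.2), 0.2 - 0.2 * 0.5^12)
  expect_equal(excluded_volume_energy(8, 4), 0)
  expect_equal(excluded_volume_energy(9.7, 4), 0)
  r <- seq(2, 7.9, by = 0.1)
  expect_true(all(diff(excluded_volume_energy(r, 4)) < 0))
})

test_that("statistical local energy: flat tables, periodicity, term oracle", {
  ff <- default_forcefield()
  dm <- domain_map("NTD", 1, 9, folded = FALSE)
  topo <- build_protein_topology("KADEAHRAA", dm, ff = ff)
  set.seed(11)
  x <- topo$coords + matrix(rnorm(27, sd = 0.4), 9, 3)
  flat <- list(angle = matrix(0, 1, 37), dihedral = matrix(0, 1, 36))
  expect_equal(statistical_local_energy(topo, x, flat), 0)
  # periodicity of the dihedral table interpolant
  tab <- default_local_tables()
  for (ph in c(-2.5, 0.3, 3.0)) {
    e1 <- p53cg:::.catmull(tab$dihedral[1, ], -pi, 2 * pi / 36, TRUE, ph)
    e2 <- p53cg:::.catmull(tab$dihedral[1, ], -pi, 2 * pi / 36, TRUE,
                           ph + 2 * pi)
    expect_equal(e1, e2, tolerance = 1e-12)
  }
  # total equals the independent sum over triples/quadruples
  acc <- 0
  for (t in seq_len(nrow(topo$angles))) {
    th <- p53cg:::.angle_of(x, unlist(topo$angles[t, c("i", "j", "k")]))
    acc <- acc + p53cg:::.catmull(tab$angle[1, ], 0, pi / 36, FALSE, th)
  }
  for (t in seq_len(nrow(topo$dihedrals))) {
    ph <- p53cg:::.dihedral_of(x, unlist(topo$dihedrals[t, c("i", "j", "k",
                                                             "l")]))
    acc <- acc + p53cg:::.catmull(tab$dihedral[1, ], -pi, 2 * pi / 36, TRUE,
                                  ph)
  }
  expect_equal(statistical_local_energy(topo, x, tab), acc,
               tolerance = 1e-10)
  # R reference path agrees with the compiled kernel
  topo0 <- topo; topo0$bonds$kf <- 0
  eC <- total_energy(build_sim_system(topo0, ff), x)
  expect_equal(eC$breakdown[["local_disordered"]],
               statistical_local_energy(topo, x, ff$tables),
               tolerance = 1e-9)
})

test_that("linker pair energy: additivity, minimum depth, linearity", {
  ff <- default_forcefield()
  dm <- domain_map(c("Core", "Linker"), c(1, 7), c(6, 14),
                   folded = c(TRUE, FALSE), linker = c(FALSE, TRUE))
  xyz <- p53cg:::.helix_coords(6)
  topo <- build_protein_topology("AAAAAAKAAEAAAA", dm,
                                 native_coords = list(Core = xyz), ff = ff)
  x <- topo$coords
  # one designated pair exactly at its native distance
  r0 <- sqrt(sum((x[8, ] - x[12, ])^2))
  topo$contacts <- rbind_contacts(
    topo$contacts, cg_contacts(8L, 12L, r0, 0.3, "linker"))
  le <- linker_pair_energy(topo, x, ff$tables)
  expect_equal(le$pairs, -0.3)
  expect_equal(le$total, le$pairs + le$local)
  # eps = 0 leaves only the statistical part
  le0 <- linker_pair_energy(topo, x, ff$tables, eps_scale = 0)
  expect_equal(le0$pairs, 0)
  expect_equal(le0$total, le0$local)
  # doubling eps doubles the pair sum at fixed coordinates
  set.seed(3)
  xr <- x + matrix(rnorm(length(x), sd = 0.4), nrow(x), 3)
  expect_equal(linker_pair_energy(topo, xr, ff$tables, eps_scale = 2)$pairs,
               2 * linker_pair_energy(topo, xr, ff$tables)$pairs,
               tolerance = 1e-12)
  # missing linker labels
  dm2 <- domain_map("NTD", 1, 5, folded = FALSE)
  topo2 <- build_protein_topology("AAAAA", dm2, ff = ff)
  expect_error(linker_pair_energy(topo2, topo2$coords), "linker")
})

test_that("DNA energy: B-form is the bonded minimum; pairing is local", {
  ff <- default_forcefield()
  ff$ev$eps <- 0   # isolate bonded + stacking + pairing
  topo <- build_dna_topology(p53cg:::re_sequence(20), ff = ff)
  topo0 <- topo; topo0$beads$charge <- 0
  e <- total_energy(build_sim_system(topo0, ff), topo0$coords,
                    forces = TRUE)
  expect_equal(e$breakdown[["dna_bonded"]], 0, tolerance = 1e-9)
  expect_lt(max(abs(e$forces)), 1e-6)   # construction geometry is stationary
  # single strand: no base-pair terms
  ss <- build_dna_topology("ACGTACGT", duplex = FALSE)
  expect_false(any(ss$contacts$cat == "dna_pair"))
  expect_true(any(ss$contacts$cat == "dna_stack"))
  # AT pairs weaker than GC pairs
  expect_lt(ff$dna$eps_bp_AT, ff$dna$eps_bp_GC)
  # pulling the strands apart kills pairing, leaves stacking unchanged
  n1 <- topo$strand_offset
  xfar <- topo$coords
  xfar[(n1 + 1):nrow(xfar), 1] <- xfar[(n1 + 1):nrow(xfar), 1] + 100
  stack <- topo$contacts$cat == "dna_stack"
  pair <- topo$contacts$cat == "dna_pair"
  dsum <- function(x, sel) {
    cc <- topo$contacts[sel, ]
    r <- sqrt(rowSums((x[cc$i, , drop = FALSE] - x[cc$j, , drop = FALSE])^2))
    sum(contact_energy(r, cc$r0, cc$eps))
  }
  expect_equal(dsum(xfar, stack), dsum(topo$coords, stack),
               tolerance = 1e-9)
  expect_equal(dsum(xfar, pair), 0, tolerance = 1e-6)
  # stacking/pairing lists only reference base beads
  bad <- topo
  bad$contacts$i[which(stack)[1]] <-
    which(topo$beads$kind == "S")[1]
  expect_error(dna_energy(bad, bad$coords, ff), "non-base")
})

test_that("total energy: decomposition sums exactly; trivial dimer", {
  ff <- default_forcefield()
  dim2 <- harmonic_dimer(kf = 50, r0 = 3.8)
  x <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  e <- total_energy(dim2$sys, x, forces = TRUE)
  expect_equal(e$total, 0)
  expect_equal(max(abs(e$forces)), 0)
  fx <- make_toy_fixture("mini_core_dna", seed = 3, ff = ff)
  sys <- build_sim_system(fx$topology, ff)
  set.seed(21)
  xr <- fx$coords + matrix(rnorm(length(fx$coords), sd = 0.25),
                           nrow(fx$coords), 3)
  er <- total_energy(sys, xr)
  expect_equal(sum(er$breakdown), er$total)
  expect_error(total_energy(sys, xr * NA), "non-finite")
})

test_that("mini Core-RE fixture at reference: contact slice = -sum(eps)", {
  ff <- default_forcefield()
  fx <- make_toy_fixture("mini_core_dna", seed = 3, ff = ff)
  sys <- build_sim_system(fx$topology, ff)
  e <- total_energy(sys, fx$coords)
  expect_equal(e$breakdown[["contacts_CoreRE"]],
               -sum(fx$core_contacts[[1]]$eps), tolerance = 1e-9)
})

test_that("forces match central finite differences for every category", {
  ff <- default_forcefield()
  # a fixture exercising every term category at once
  fx <- make_toy_fixture("tetramer_toy", seed = 5, ff = ff)
  sys <- build_sim_system(
    fx$topology, ff,
    container = list(center = c(0, 0, 50), radius = 80, k = 10),
    bias = list(groupA = fx$core_beads[[1]], groupB = fx$quarter_beads[[1]],
                k = 1, r0 = 12, half = TRUE))
  set.seed(31)
  x <- fx$coords + matrix(rnorm(length(fx$coords), sd = 0.25),
                          nrow(fx$coords), 3)
  idx <- cbind(sample(nrow(x), 120, replace = TRUE),
               sample(3, 120, replace = TRUE))
  expect_lt(fd_force_error(sys, x, idx = idx), 1e-4)
})

test_that("energy is invariant under rigid-body transforms", {
  ff <- default_forcefield()
  fx <- make_toy_fixture("mini_core_dna", seed = 7, ff = ff)
  sys <- build_sim_system(fx$topology, ff)
  set.seed(8)
  x <- fx$coords + matrix(rnorm(length(fx$coords), sd = 0.2),
                          nrow(fx$coords), 3)
  e1 <- total_energy(sys, x)$total
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ax <- 0.41
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), -sin(ax), 0, sin(ax), cos(ax)), 3, 3)
  x2 <- sweep(x %*% R %*% Rx, 2, c(7.3, -4.1, 11.8), "+")
  e2 <- total_energy(sys, x2)$total
  expect_lt(abs(e2 - e1), 1e-8)
})
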