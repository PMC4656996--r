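test_that("nearest distance: trivial cases and brute-force agreement", {
  set.seed(17)
  nf <- 100
  frames <- array(rnorm(20 * 3 * nf, sd = 10), c(20, 3, nf))
  one <- nearest_distance(frames, 5, 5)
  expect_true(all(one$distance == 0))
  # static two beads at 5 A
  fr2 <- array(rep(rbind(c(0, 0, 0), c(5, 0, 0)), 3), c(2, 3, 3))
  expect_true(all(nearest_distance(fr2, 1, 2)$distance == 5))
  # brute force oracle on random frames
  gA <- 1:7; gB <- 11:20
  nd <- nearest_distance(frames, gA, gB)
  for (f in seq_len(nf)) {
    brute <- min(as.matrix(dist(frames[, , f]))[gA, gB])
    expect_equal(nd$distance[f], brute, tolerance = 1e-12)
  }
  expect_error(nearest_distance(frames, integer(0), gB), "empty")
})

test_that("qscore counts satisfied contacts with the tolerance factor", {
  xyz <- p53cg:::.helix_coords(16)
  cm <- native_contact_map(xyz, 6.5, 4)
  expect_equal(qscore(xyz, cm), 1)
  expect_equal(qscore(xyz * 10, cm), 0)
  # constructed 4-contact list with exactly 2 satisfied
  x <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(5, 5, 0), c(10, 10, 10))
  cl <- cg_contacts(c(1L, 1L, 1L, 2L), c(2L, 3L, 5L, 5L),
                    r0 = c(5, 5, 5, 5), eps = rep(1, 4),
                    cat = rep("intra", 4))
  expect_equal(qscore(x, cl, tol = 1.2), 0.5)
  expect_error(qscore(x, cl[0, ]), "empty")
  expect_error(qscore(x, cl, tol = 0.9), "tol")
  # range invariant
  set.seed(2)
  for (i in 1:10) {
    q <- qscore(x + matrix(rnorm(15, sd = 3), 5, 3), cl)
    expect_gte(q, 0); expect_lte(q, 1)
  }
})

test_that("bend score: straight helix exactly 1, hinge gives cos(theta)", {
  fx <- make_toy_fixture("free_dna", params = list(dna_bp = 41))
  prof <- bend_score(fx$coords, fx$topology, w = 10)
  expect_equal(prof$bp, 11:31)
  expect_true(all(abs(prof$score - 1) < 1e-10))
  # synthetic hinge: strand-1 sugar beads on two straight arms meeting at
  # angle theta at the hinge base pair (closed-form expectation)
  topo <- fx$topology
  n <- 41
  s_idx <- dna_sugar_indices(topo, 1)
  x <- fx$coords
  theta <- 35 * pi / 180
  hinge <- 21
  for (i in seq_len(n)) {
    if (i <= hinge) x[s_idx[i], ] <- c(0, 0, (i - 1) * 3.38)
    else x[s_idx[i], ] <- c(sin(theta), 0, cos(theta)) * 3.38 *
        (i - hinge) + c(0, 0, (hinge - 1) * 3.38)
  }
  prof2 <- bend_score(x, topo, w = 10)
  expect_equal(prof2$score[prof2$bp == hinge], cos(theta),
               tolerance = 1e-10)
  # away from the hinge the arms are exactly straight
  expect_equal(prof2$score[prof2$bp == 11], 1, tolerance = 1e-10)
  expect_equal(prof2$score[prof2$bp == 31], 1, tolerance = 1e-10)
  # rigid rotation leaves the profile unchanged
  th <- 0.9
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  prof3 <- bend_score(sweep(x %*% Rz, 2, c(3, -8, 2), "+"), topo, w = 10)
  expect_equal(prof3$score, prof2$score, tolerance = 1e-10)
  expect_error(bend_score(fx$coords, fx$topology, w = 25), "shorter")
})

test_that("bound-core assignment counts transitions with hysteresis", {
  fx <- make_toy_fixture("tetramer_toy", seed = 9)
  frames <- array(fx$coords, c(nrow(fx$coords), 3, 2))
  bs <- assign_bound_cores(frames, fx$core_contacts)
  expect_true(all(bs$series$n_bound == 4))
  # constructed Q series: move one core away then back is suppressed by
  # hysteresis; use synthetic coordinates crossing 0.5 once
  far <- fx$coords
  far[fx$core_beads[[1]], 1] <- far[fx$core_beads[[1]], 1] + 50
  frames2 <- array(c(far, fx$coords), c(nrow(far), 3, 2))
  bs2 <- assign_bound_cores(frames2, fx$core_contacts)
  expect_equal(bs2$series$n_bound, c(3, 4))
  expect_equal(nrow(bs2$transitions), 1)
  expect_equal(bs2$transitions$from, 3)
  expect_equal(bs2$transitions$to, 4)
  expect_error(assign_bound_cores(frames2, fx$core_contacts, q_on = 1.2),
               "thresholds")
})

test_that("hysteresis suppresses flicker around the threshold", {
  # one core, one contact; distance oscillating so plain Q flips but the
  # 0.6/0.4 band records nothing
  cl <- list(cg_contacts(1L, 2L, 10, 1, "core_re"))
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  ds <- c(11, 13, 11, 13, 11)   # Q alternates 1, 0 with tol 1.2
  frames <- array(vapply(ds, mk, matrix(0, 2, 3)), c(2, 3, length(ds)))
  plain <- assign_bound_cores(frames, cl, q_on = 0.5)
  expect_gt(nrow(plain$transitions), 1)
  # under hysteresis, Q alternating within [0.45, 0.55] yields no flips:
  # with a 2-contact list, Q oscillates between 0.5 and 0.5 exactly; use
  # thresholds 0.6 / 0.4 so the band swallows the oscillation
  cl2 <- list(cg_contacts(c(1L, 1L), c(2L, 3L), c(10, 10), c(1, 1),
                          c("core_re", "core_re")))
  mk2 <- function(d) rbind(c(0, 0, 0), c(10, 0, 0), c(d, 3, 0))
  # frame 1 unbound (Q = 0.5 < q_on), then the second contact toggles so
  # Q alternates between 1 and 0.5 inside the hysteresis band
  ds2 <- c(20, 10, 14, 10, 14)
  fr2 <- array(vapply(ds2, mk2, matrix(0, 3, 3)), c(3, 3, length(ds2)))
  hyst <- assign_bound_cores(fr2, cl2, q_on = 0.6, q_off = 0.4)
  expect_equal(nrow(hyst$transitions), 1)   # binds once, never unbinds
})

test_that("survival fit recovers tau on synthetic exponential lifetimes", {
  set.seed(99)
  d <- rexp(1000, rate = 1 / 10)
  fit <- survival_fit(d)
  expect_gt(fit$tau, 9); expect_lt(fit$tau, 11)
  expect_equal(fit$rate, 1 / fit$tau)
  expect_gt(fit$r_squared, 0.98)
  # scale equivariance
  fit2 <- survival_fit(d * 2)
  expect_equal(fit2$tau, 2 * fit$tau, tolerance = 1e-9)
  # censoring: censored runs lower the event count, not the estimate scale
  cens <- c(rep(FALSE, 900), rep(TRUE, 100))
  fitc <- survival_fit(d, censored = cens)
  expect_equal(fitc$n_events, 900)
  expect_gt(fitc$tau, 8); expect_lt(fitc$tau, 13)
  # MLE flag
  fitm <- survival_fit(d, mle = TRUE)
  expect_equal(fitm$tau, mean(d), tolerance = 1e-9)
  expect_error(survival_fit(rep(3, 10)), "identical")
  expect_error(survival_fit(c(1, 2)), "at least 5")
})

test_that("tau recovery is within 3 SE across 20 seeds", {
  z <- vapply(1:20, function(s) {
    set.seed(s)
    d <- rexp(400, rate = 1 / 10)
    f <- survival_fit(d)
    abs(f$tau - 10) / f$se_tau
  }, numeric(1))
  expect_true(all(z < 3))
})

test_that("a two-exponential mixture trips the misfit flag", {
  set.seed(1)
  single <- survival_fit(rexp(600, 1 / 10))
  mix <- survival_fit(c(rexp(300, 1), rexp(300, 1 / 50)))
  expect_gt(mix$fit_residual, 3 * single$fit_residual)
  expect_lt(mix$r_squared, single$r_squared)
})

test_that("histogram PMF: uniform flatness, Boltzmann recovery, scaling", {
  x <- rep(seq(0.25, 9.75, by = 0.5), each = 20)
  pmf <- pmf_from_histogram(x, breaks = 0.5)
  expect_true(all(abs(pmf$F[pmf$count > 0]) < 1e-12))
  # doubling all counts leaves F unchanged
  pmf2 <- pmf_from_histogram(c(x, x), breaks = 0.5)
  expect_equal(pmf$F, pmf2$F)
  # samples from a harmonic Boltzmann weight recover U within 0.1
  set.seed(12)
  sig <- sqrt(kB * 300 / 2)           # U = (1/2) * 2 * (x-10)^2
  xs <- rnorm(2e5, 10, sig)
  pmf3 <- pmf_from_histogram(xs, breaks = 0.1, temperature = 300)
  sel <- pmf3$count > 500
  ref <- 0.5 * 2 * (pmf3$r - 10)^2
  err <- abs((pmf3$F - min(pmf3$F[sel])) - (ref - min(ref[sel])))
  expect_lt(max(err[sel]), 0.1)
  # empty bins are NA, not zero
  gapx <- c(1.1, 1.2, 5.1, 5.3)
  pg <- pmf_from_histogram(gapx, breaks = 0.5)
  expect_true(anyNA(pg$F))
  expect_error(pmf_from_histogram(numeric(0)), "empty")
})

test_that("connectivity classifier maps the three canonical pairings", {
  partners <- c(2L, 1L, 4L, 3L)
  expect_equal(classify_connectivity(c(1, 3, 2, 4), partners)$type, 1L)
  expect_equal(classify_connectivity(c(1, 4, 2, 3), partners)$type, 2L)
  expect_equal(classify_connectivity(c(1, 2, 3, 4), partners)$type, 3L)
  # label-permutation invariance across all 24 relabelings
  base <- expand.grid(1:3)
  qs <- list(c(1, 3, 2, 4), c(1, 4, 2, 3), c(1, 2, 3, 4))
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  for (ti in 1:3) {
    q <- qs[[ti]]
    for (r in seq_len(nrow(perms))) {
      p <- perms[r, ]; inv <- order(p)
      expect_equal(classify_connectivity(q[p], inv[partners[p]])$type, ti)
    }
  }
  expect_error(classify_connectivity(c(1, 1, 3, 4), partners),
               "permutation")
  expect_error(classify_connectivity(c(1, 2, 3, 4), c(2L, 1L, 3L, 4L)),
               "pair")
})

test_that("frame-level typing skips incompletely bound frames", {
  fx <- make_toy_fixture("tetramer_toy", seed = 9)
  ty <- classify_frame(fx$coords, fx$core_beads, fx$quarter_beads,
                       fx$tet_partner)
  expect_equal(ty$type, 3L)   # construction pairs partners on a half-site
  far <- fx$coords
  far[fx$core_beads[[2]], ] <- far[fx$core_beads[[2]], ] + 80
  expect_true(is.na(classify_frame(far, fx$core_beads, fx$quarter_beads,
                                   fx$tet_partner)))
  expect_error(classify_frame(far, fx$core_beads, fx$quarter_beads,
                              fx$tet_partner, strict = TRUE), "fewer")
})

test_that("occupancy grid: static point, normalization, centroid recovery", {
  pt <- matrix(c(1, 2, 3), 1, 3)
  frames <- array(rep(t(pt), 5), c(1, 3, 5))
  g <- occupancy_grid(frames, 1, voxel = 2)
  expect_equal(sum(g$prob), 1)
  expect_equal(max(g$prob), 1)
  set.seed(33)
  nf <- 4000
  cloud <- array(0, c(2, 3, nf))
  mu <- c(5, -3, 12)
  for (f in seq_len(nf))
    cloud[, , f] <- rbind(mu + rnorm(3, sd = 4), mu + rnorm(3, sd = 4))
  g2 <- occupancy_grid(cloud, 1:2, voxel = 2)
  expect_equal(sum(g2$prob), 1, tolerance = 1e-12)
  # probability-weighted voxel-center mean close to the true mean
  idx <- which(g2$counts > 0, arr.ind = TRUE)
  cent <- sweep((idx - 0.5) * g2$voxel, 2, g2$origin, "+")
  wmean <- colSums(cent * g2$prob[idx])
  true_mean <- colMeans(t(apply(cloud, 3, function(fr) colMeans(fr))))
  expect_lt(sqrt(sum((wmean - true_mean)^2)), 0.5)
  expect_error(occupancy_grid(array(0, c(2, 3, 0)), 1:2), "empty")
})
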