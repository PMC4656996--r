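test_that("umbrella window construction validates its grid", {
  w <- umbrella_windows(seq(4, 27, by = 1), k = 1.0)
  expect_equal(nrow(w), 24)
  expect_true(all(diff(w$center) == 1))
  expect_error(umbrella_windows(c(4, 4, 5)), "increasing")
  expect_error(umbrella_windows(c(4, 5), k = 0))
})

test_that("identical windows always accept their swap", {
  w <- umbrella_windows(c(10, 10 + 1e-12), k = 1.0)
  att <- p53cg:::.attempt_swaps(c(9.3, 11.2), w, beta = 1 / (kB * 300),
                                parity = 0, unif = runif(2))
  expect_true(all(att$accepted))
  expect_true(all(abs(att$delta) < 1e-9))
})

test_that("1-D REUS on a double well: WHAM recovers the potential", {
  coef <- double_well_coef()
  w <- umbrella_windows(seq(4, 27, by = 1), k = 1.0)
  lp <- langevin_params(dt = 0.05, gamma = 1.0, temperature = 300, seed = 3)
  re <- reus_1d(coef, w, params = lp, mass = 1, n_rounds = 300,
                steps_per_round = 2000, rc_stride = 10)
  expect_gt(re$acceptance_rate, 0.1)
  # window -> replica assignment stays a bijection at every exchange step
  expect_true(all(apply(re$perm_history, 1,
                        function(p) identical(sort(p), 1:24))))
  pm <- wham(re, breaks = 0.25)
  sel <- pm$count > 100
  ref <- double_well_bin_F(c(pm$r - 0.125, tail(pm$r, 1) + 0.125))
  expect_lt(max(abs((pm$F[sel] - min(pm$F[sel])) -
                      (ref[sel] - min(ref[sel])))), 0.15)
  # detailed-balance audit: agreement with a long unbiased run
  out <- p53cg:::cpp_run_1d(coef, 0, 0, 0.5, 14, 0, 8e6, 0.05, 1.0, 300, 1,
                            12345, 0L, 10L)
  pmf_direct <- pmf_from_histogram(out$samples, breaks = 0.25)
  m <- merge(as.data.frame(pm), as.data.frame(pmf_direct), by = "r")
  m <- m[m$count.x > 500 & m$count.y > 500, ]
  expect_gt(nrow(m), 10)
  dF <- (m$F.x - min(m$F.x)) - (m$F.y - min(m$F.y))
  expect_lt(max(abs(dF)), 0.1)
})

test_that("WHAM is invariant to window order and handles a single window", {
  coef <- double_well_coef()
  w <- umbrella_windows(seq(6, 22, by = 1), k = 1.0)
  lp <- langevin_params(dt = 0.05, gamma = 1.0, temperature = 300, seed = 5)
  re <- reus_1d(coef, w, params = lp, mass = 1, n_rounds = 80,
                steps_per_round = 1500, rc_stride = 10)
  pm1 <- wham(re, breaks = 0.5)
  hs <- rev(re$histograms)
  pm2 <- wham(hs, breaks = 0.5, temperature = 300)
  expect_equal(pm1$F, pm2$F, tolerance = 1e-6)
  # single window with zero-ish bias reduces to the plain histogram PMF
  h1 <- list(list(center = 14, k = 1e-12, half = TRUE,
                  samples = re$histograms[[8]]$samples))
  pmw <- wham(h1, breaks = 0.5, temperature = 300)
  pmh <- pmf_from_histogram(re$histograms[[8]]$samples, breaks = 0.5)
  expect_equal(pmw$F, pmh$F, tolerance = 1e-6)
  # non-overlapping windows are reported
  gap <- list(re$histograms[[1]], re$histograms[[17]])
  expect_error(wham(gap, breaks = 0.5, temperature = 300),
               "non-overlapping")
})

test_that("3-D REUS machinery biases the molecular reaction coordinate", {
  ff <- default_forcefield()
  fx <- make_toy_fixture("mini_core_dna", seed = 3, ff = ff)
  fx <- fix_dna_ends(fx)
  sys <- build_sim_system(
    fx$topology, ff,
    bias = list(groupA = fx$core_beads[[1]],
                groupB = unique(c(fx$quarter_beads[[1]],
                                  fx$quarter_beads[[2]])),
                k = 0, r0 = 0, half = TRUE))
  w <- umbrella_windows(c(8, 10, 12, 14), k = 2.0)
  lp <- langevin_params(dt = 0.05, gamma = 0.2, temperature = 300, seed = 2)
  re <- run_reus(sys, w, sim_state(fx$coords), lp, n_rounds = 10,
                 steps_per_round = 500, rc_stride = 25)
  expect_equal(length(re$histograms), 4)
  expect_true(all(vapply(re$histograms,
                         function(h) length(h$samples) > 0, TRUE)))
  # low and high windows separate along the coordinate
  means <- vapply(re$histograms, function(h) mean(h$samples), numeric(1))
  expect_lt(means[1], means[4])
  expect_true(all(apply(re$perm_history, 1,
                        function(p) identical(sort(p), 1:4))))
})
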