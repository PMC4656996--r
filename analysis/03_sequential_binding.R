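#!/usr/bin/env Rscript
# Sequential recognition: starting from displaced (unbound) Cores, the
# tetramer toy binds its four quarter-sites one by one. Records the
# bound-core count, fits single exponentials to the intermediate-state
# lifetimes, and writes the per-state rate table plus an approximate free
# energy (PMF) along the nearest unbound-Core/RE distance.

library(p53cg)

seed <- 1
n_runs <- 10
nsteps <- 8e5
outdir <- "results"
dir.create(outdir, showWarnings = FALSE)
ff <- default_forcefield()

lifetimes <- list(`0` = c(), `1` = c(), `2` = c(), `3` = c())
cens <- list(`0` = c(), `1` = c(), `2` = c(), `3` = c())
nd_pool <- list()
summary_rows <- list()

for (r in seq_len(n_runs)) {
  fx <- fix_dna_ends(make_toy_fixture("tetramer_toy", seed = seed + r,
                                      ff = ff, start = "unbound"))
  sys <- build_sim_system(fx$topology, ff)
  lp <- langevin_params(dt = 0.1, gamma = 0.02, temperature = 300,
                        seed = seed * 1000 + r)
  traj <- run_simulation(sys, fx$coords, lp, nsteps, stride = 2000)
  bs <- assign_bound_cores(traj, fx$core_contacts, q_on = 0.5, q_off = 0.35)
  nb <- bs$series$n_bound
  # dwell times in each intermediate (censored if the run ends there)
  dt_frame <- diff(bs$series$step[1:2]) * lp$dt
  runs <- rle(nb)
  tend <- cumsum(runs$lengths)
  for (k in seq_along(runs$values)) {
    s <- as.character(runs$values[k])
    if (!s %in% names(lifetimes)) next
    dur <- runs$lengths[k] * dt_frame
    censored <- k == length(runs$values)
    lifetimes[[s]] <- c(lifetimes[[s]], dur)
    cens[[s]] <- c(cens[[s]], censored)
  }
  # nearest distance between the least-bound Core and the RE
  qmin <- apply(bs$q, 1, which.min)
  re_beads <- unique(unlist(fx$quarter_beads))
  nd <- vapply(seq_len(n_frames(traj)), function(f) {
    cb <- fx$core_beads[[qmin[f]]]
    min(sqrt(colSums((t(get_frame(traj, f)[re_beads, ]) -
                        colMeans(get_frame(traj, f)[cb, , drop = FALSE]))^2)))
  }, numeric(1))
  nd_pool[[r]] <- nd[nb == 3]
  summary_rows[[r]] <- data.frame(
    run = r, final_n_bound = tail(nb, 1), reached4 = any(nb == 4),
    sequential = monotone_since_last_zero(bs$transitions))
  cat(sprintf("run %2d: final bound count %d, transitions %s\n", r,
              tail(nb, 1),
              paste(bs$transitions$to, collapse = ">")))
}

summ <- do.call(rbind, summary_rows)
write_tsv(summ, file.path(outdir, "binding_runs.tsv"),
          comment = "sequential-binding demonstration runs")
cat(sprintf("\n%d/%d runs reached the 4-bound state sequentially\n",
            sum(summ$sequential & summ$reached4), n_runs))

cat("\nintermediate-state lifetime fits (single exponential):\n")
rates <- list()
for (s in c("1", "2", "3")) {
  d <- lifetimes[[s]]; cc <- cens[[s]]
  if (length(d) >= 5 && sum(!cc) >= 3 && length(unique(d)) > 1) {
    f <- try(survival_fit(d, censored = cc, mle = TRUE), silent = TRUE)
    if (!inherits(f, "try-error")) {
      cat(sprintf("  %s-bound state: n = %2d, tau = %8.1f, k = %.2e /unit\n",
                  s, length(d), f$tau, f$rate))
      rates[[s]] <- data.frame(state = as.integer(s), n = length(d),
                               tau = f$tau, rate = f$rate)
    }
  } else {
    cat(sprintf("  %s-bound state: too few dwells (n = %d) for a fit\n",
                s, length(d)))
  }
}
if (length(rates))
  write_tsv(do.call(rbind, rates), file.path(outdir, "binding_rates.tsv"),
            comment = "1/tau rate estimates per intermediate state")

nd_all <- unlist(nd_pool)
if (length(nd_all) > 50) {
  pmf <- pmf_from_histogram(nd_all, breaks = 1, temperature = 300)
  write_tsv(pmf, file.path(outdir, "pmf_nearest_distance_3bound.tsv"),
            comment = c("approximate free energy along the nearest",
                        "unbound-Core/RE distance in the 3-bound state"))
  cat(sprintf("\nPMF written over %d samples, %d occupied bins\n",
              length(nd_all), sum(pmf$count > 0)))
}
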