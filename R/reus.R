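#' Umbrella window set
#'
#' Harmonic bias \eqn{U_i(r) = \tfrac12 k (r - r_i^0)^2} (set `half = FALSE`
#' for the convention without the 1/2). Centers must be strictly
#' increasing. The production grid is centers 4.0..27.0 A at 1 A intervals
#' with k = 1.0 kcal/mol/A^2.
#'
#' @param centers bias centers in Angstrom, strictly increasing.
#' @param k spring constant(s), kcal/mol/A^2 (> 0).
#' @param half logical: include the 1/2 factor (default TRUE).
#' @return data.frame of class `cg_windows`.
#' @export
umbrella_windows <- function(centers = seq(4, 27, by = 1), k = 1.0,
                             half = TRUE) {
  stopifnot(all(k > 0))
  if (any(diff(centers) <= 0)) stop("window centers must be strictly increasing")
  w <- data.frame(center = centers, k = rep_len(k, length(centers)))
  attr(w, "half") <- half
  class(w) <- c("cg_windows", "data.frame")
  w
}

.bias_u <- function(r, center, k, half) (if (half) 0.5 else 1) * k * (r - center)^2

# one odd/even alternating neighbor-swap sweep; states labelled by window.
# rc: current reaction coordinate per window's state. Returns the list of
# attempted pairs with Metropolis outcome (uniforms supplied by caller).
.attempt_swaps <- function(rc, windows, beta, parity, unif) {
  K <- nrow(windows)
  first <- if (parity %% 2 == 0) 1 else 2
  idx <- seq(first, K - 1, by = 2)
  half <- attr(windows, "half")
  out <- data.frame(i = integer(0), j = integer(0), delta = numeric(0),
                    p_accept = numeric(0), accepted = logical(0))
  for (t in seq_along(idx)) {
    i <- idx[t]; j <- i + 1
    delta <- beta * (.bias_u(rc[j], windows$center[i], windows$k[i], half) +
                     .bias_u(rc[i], windows$center[j], windows$k[j], half) -
                     .bias_u(rc[i], windows$center[i], windows$k[i], half) -
                     .bias_u(rc[j], windows$center[j], windows$k[j], half))
    p <- min(1, exp(-delta))
    out <- rbind(out, data.frame(i = i, j = j, delta = delta, p_accept = p,
                                 accepted = unif[t] < p))
  }
  out
}

#' Replica-exchange umbrella sampling over a centroid-distance coordinate
#'
#' Each window runs Langevin dynamics under its harmonic bias on the
#' distance between the two bead-group centroids defined in `sys$bias`;
#' after every `steps_per_round` steps, neighboring windows attempt
#' Metropolis swaps (alternating odd/even pairs). Swapping exchanges the
#' configurations between windows, so the window->replica assignment stays
#' a bijection.
#'
#' @param sys `cg_system` built with `bias = list(groupA=, groupB=, ...)`
#'   (the window parameters override `k`/`r0`).
#' @param windows `cg_windows` (>= 2 rows).
#' @param state0 initial `cg_state`, or a list of one state per window.
#' @param params `cg_langevin_params`; the master seed also drives the
#'   swap decisions and derives one noise stream per replica.
#' @param n_rounds exchange attempts; @param steps_per_round steps between
#'   attempts; @param rc_stride reaction-coordinate sampling interval.
#' @return list of class `cg_reus`: `histograms` (per window: center, k,
#'   samples), `exchange_log`, `acceptance_rate`, `perm_history` (window ->
#'   replica id each round), `windows`.
#' @export
run_reus <- function(sys, windows, state0, params, n_rounds = 50,
                     steps_per_round = 1000, rc_stride = 10) {
  K <- nrow(windows)
  if (K < 2) stop("need >= 2 windows")
  if (!length(sys$bias$groupA) || !length(sys$bias$groupB))
    stop("sys must define bias groups for the reaction coordinate")
  states <- if (inherits(state0, "cg_state"))
    replicate(K, state0, simplify = FALSE) else state0
  stopifnot(length(states) == K)
  half <- attr(windows, "half")
  syss <- lapply(seq_len(K), function(w) {
    s <- sys
    s$bias$has <- TRUE; s$bias$k <- windows$k[w]
    s$bias$r0 <- windows$center[w]; s$bias$half <- half
    s
  })
  replica_of <- seq_len(K)      # window -> replica id
  seeds <- as.numeric(params$seed) * 10007 + seq_len(K)
  set.seed(as.integer(params$seed %% .Machine$integer.max))
  samples <- vector("list", K)
  xlog <- list(); perm <- matrix(NA_integer_, n_rounds, K)
  beta <- 1 / (.kB * params$temperature)
  rc_last <- rep(NA_real_, K)
  for (round in seq_len(n_rounds)) {
    for (w in seq_len(K)) {
      p <- params; p$seed <- seeds[replica_of[w]]
      traj <- run_simulation(syss[[w]], states[[w]], p, steps_per_round,
                             stride = 0, rc_stride = rc_stride)
      states[[w]] <- traj$state
      samples[[w]] <- c(samples[[w]], traj$rc)
      rc_last[w] <- tail(traj$rc, 1)
    }
    att <- .attempt_swaps(rc_last, windows, beta, parity = round,
                          unif = runif(K))
    att$round <- round
    for (t in seq_len(nrow(att))) {
      if (att$accepted[t]) {
        i <- att$i[t]; j <- att$j[t]
        tmp <- states[[i]]; states[[i]] <- states[[j]]; states[[j]] <- tmp
        replica_of[c(i, j)] <- replica_of[c(j, i)]
        rc_last[c(i, j)] <- rc_last[c(j, i)]
      }
    }
    xlog[[round]] <- att
    perm[round, ] <- replica_of
  }
  xl <- do.call(rbind, xlog)
  hist_list <- lapply(seq_len(K), function(w)
    list(center = windows$center[w], k = windows$k[w], half = half,
         samples = samples[[w]]))
  if (any(vapply(hist_list, function(h) length(h$samples) == 0, TRUE)))
    stop("empty histogram in at least one window")
  structure(list(histograms = hist_list, exchange_log = xl,
                 acceptance_rate = mean(xl$accepted),
                 perm_history = perm, windows = windows,
                 temperature = params$temperature),
            class = "cg_reus")
}

#' Replica-exchange umbrella sampling of a 1-D polynomial potential
#'
#' Identical exchange machinery to [run_reus()], but the replicas are 1-D
#' Langevin particles on an analytic polynomial potential. This is the
#' ground-truth path used to audit WHAM against a known free-energy
#' profile.
#'
#' @param coef polynomial coefficients of U(x), constant term first.
#' @param windows `cg_windows`; @param x0 initial position (recycled);
#' @param params `cg_langevin_params`; @param mass particle mass;
#' @param n_rounds,steps_per_round,rc_stride as in [run_reus()].
#' @return `cg_reus` (histograms carry x samples).
#' @export
reus_1d <- function(coef, windows, x0 = NULL, params = langevin_params(),
                    mass = 1, n_rounds = 50, steps_per_round = 2000,
                    rc_stride = 10) {
  K <- nrow(windows)
  if (K < 2) stop("need >= 2 windows")
  half <- attr(windows, "half")
  fac <- if (half) 0.5 else 1
  xs <- if (is.null(x0)) windows$center else rep_len(x0, K)
  vs <- rep(0, K); steps <- rep(0L, K)
  replica_of <- seq_len(K)
  seeds <- as.numeric(params$seed) * 10007 + seq_len(K)
  set.seed(as.integer(params$seed %% .Machine$integer.max))
  samples <- vector("list", K)
  xlog <- list(); perm <- matrix(NA_integer_, n_rounds, K)
  beta <- 1 / (.kB * params$temperature)
  for (round in seq_len(n_rounds)) {
    for (w in seq_len(K)) {
      out <- cpp_run_1d(coef, windows$k[w], windows$center[w], fac,
                        xs[w], vs[w], as.integer(steps_per_round),
                        params$dt, params$gamma, params$temperature, mass,
                        seeds[replica_of[w]], steps[w],
                        as.integer(rc_stride))
      xs[w] <- out$x; vs[w] <- out$v; steps[w] <- out$step
      samples[[w]] <- c(samples[[w]], out$samples)
    }
    att <- .attempt_swaps(xs, windows, beta, parity = round, unif = runif(K))
    att$round <- round
    for (t in seq_len(nrow(att))) {
      if (att$accepted[t]) {
        i <- att$i[t]; j <- att$j[t]
        xs[c(i, j)] <- xs[c(j, i)]; vs[c(i, j)] <- vs[c(j, i)]
        steps[c(i, j)] <- steps[c(j, i)]
        replica_of[c(i, j)] <- replica_of[c(j, i)]
      }
    }
    xlog[[round]] <- att
    perm[round, ] <- replica_of
  }
  xl <- do.call(rbind, xlog)
  hist_list <- lapply(seq_len(K), function(w)
    list(center = windows$center[w], k = windows$k[w], half = half,
         samples = samples[[w]]))
  structure(list(histograms = hist_list, exchange_log = xl,
                 acceptance_rate = mean(xl$accepted),
                 perm_history = perm, windows = windows,
                 temperature = params$temperature),
            class = "cg_reus")
}
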