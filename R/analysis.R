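#' Nearest distance between two bead groups along a trajectory
#'
#' Per frame, the minimum over all A x B pair distances (brute force).
#'
#' @param traj `cg_trajectory` (or n x 3 x f array).
#' @param groupA,groupB non-empty bead index vectors.
#' @return data.frame of class `cg_distance_series`: step, distance.
#' @export
nearest_distance <- function(traj, groupA, groupB) {
  if (!length(groupA) || !length(groupB)) stop("empty selection")
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else traj
  steps <- if (inherits(traj, "cg_trajectory")) traj$steps else
    seq_len(dim(frames)[3])
  nf <- dim(frames)[3]
  d <- vapply(seq_len(nf), function(f) {
    A <- matrix(frames[groupA, , f], ncol = 3)
    B <- matrix(frames[groupB, , f], ncol = 3)
    dx <- outer(A[, 1], B[, 1], "-")
    dy <- outer(A[, 2], B[, 2], "-")
    dz <- outer(A[, 3], B[, 3], "-")
    sqrt(min(dx^2 + dy^2 + dz^2))
  }, numeric(1))
  out <- data.frame(step = steps, distance = d)
  class(out) <- c("cg_distance_series", "data.frame")
  out
}

#' Fraction of native contacts (Q-score)
#'
#' Q = (number of contact pairs with r <= tol * r0) / (number of pairs in
#' the list). 1 at the native structure, 0 when all contacts are broken.
#'
#' @param frame n x 3 coordinate matrix.
#' @param contacts `cg_contacts` (non-empty).
#' @param tol tolerance factor (> 1; default 1.2).
#' @return Q in \[0, 1\].
#' @export
qscore <- function(frame, contacts, tol = 1.2) {
  if (!nrow(contacts)) stop("empty contact list")
  if (tol <= 1) stop("tol must exceed 1")
  d <- sqrt(rowSums((frame[contacts$i, , drop = FALSE] -
                       frame[contacts$j, , drop = FALSE])^2))
  mean(d <= tol * contacts$r0)
}

#' Q-score time series
#' @param traj trajectory; @param contacts contact list; @param tol factor.
#' @return data.frame step, q.
#' @export
qscore_series <- function(traj, contacts, tol = 1.2) {
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else traj
  steps <- if (inherits(traj, "cg_trajectory")) traj$steps else
    seq_len(dim(frames)[3])
  q <- vapply(seq_len(dim(frames)[3]),
              function(f) qscore(frames[, , f], contacts, tol), numeric(1))
  data.frame(step = steps, q = q)
}

#' DNA bending score profile
#'
#' \eqn{S_i = \langle \hat u_{i-w,i} \cdot \hat u_{i,i+w} \rangle} where
#' \eqn{\hat u_{a,b}} is the unit vector between the sugar beads at base
#' pairs a and b of one strand, averaged over frames (optionally over both
#' strands). With w = 10 bp (one helical repeat) a straight ideal helix
#' scores exactly 1 and bending lowers the score.
#'
#' @param traj trajectory or single frame matrix.
#' @param topo DNA `cg_topology` (for sugar indexing).
#' @param w half-span in bp (default 10).
#' @param both_strands average over both strands (default FALSE).
#' @return data.frame of class `cg_bend_profile`: bp, score.
#' @export
bend_score <- function(traj, topo, w = 10, both_strands = FALSE) {
  stopifnot(w >= 1)
  n <- topo$n_bp
  if (is.null(n)) stop("topology lacks DNA bp count")
  if (n < 2 * w + 1) stop("chain shorter than 2w + 1 base pairs")
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else
    if (length(dim(traj)) == 3) traj else array(traj, c(nrow(traj), 3, 1))
  strands <- if (both_strands) 1:2 else 1
  idx_by_strand <- lapply(strands, function(s) dna_sugar_indices(topo, s))
  iis <- (w + 1):(n - w)
  acc <- matrix(0, length(iis), 1)
  nf <- dim(frames)[3]
  total <- 0
  for (f in seq_len(nf)) {
    for (sidx in idx_by_strand) {
      X <- frames[sidx, , f]
      u1 <- X[iis, ] - X[iis - w, ]
      u2 <- X[iis + w, ] - X[iis, ]
      u1 <- u1 / sqrt(rowSums(u1^2))
      u2 <- u2 / sqrt(rowSums(u2^2))
      acc <- acc + rowSums(u1 * u2)
      total <- total + 1
    }
  }
  out <- data.frame(bp = iis, score = as.numeric(acc / total))
  attr(out, "w") <- w
  class(out) <- c("cg_bend_profile", "data.frame")
  out
}

#' Bound-core assignment and sequential-binding bookkeeping
#'
#' Core c is bound at a frame iff its Core--RE Q-score is at or above
#' `q_on`; with hysteresis (`q_off < q_on`) a bound core stays bound until
#' Q drops below `q_off`, suppressing threshold flicker. Records the
#' n-bound time series and the first-passage step of each i -> i+1
#' transition.
#'
#' @param traj trajectory.
#' @param core_contacts list of `cg_contacts`, one per Core (its own
#'   Core--RE sublist).
#' @param q_on on-threshold in (0,1), default 0.5.
#' @param q_off off-threshold; default `q_on` (no hysteresis).
#' @param tol Q-score tolerance factor.
#' @return list of class `cg_bound_series`: `series` (step, n_bound,
#'   per-core flags), `transitions` (from, to, step), `first_passage`
#'   (named vector, first step with n_bound >= k).
#' @export
assign_bound_cores <- function(traj, core_contacts, q_on = 0.5,
                               q_off = q_on, tol = 1.2) {
  if (q_on <= 0 || q_on >= 1 || q_off <= 0 || q_off > q_on)
    stop("thresholds must satisfy 0 < q_off <= q_on < 1")
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else traj
  steps <- if (inherits(traj, "cg_trajectory")) traj$steps else
    seq_len(dim(frames)[3])
  nf <- dim(frames)[3]; nc <- length(core_contacts)
  qm <- sapply(core_contacts, function(cc) {
    vapply(seq_len(nf), function(f) qscore(frames[, , f], cc, tol),
           numeric(1))
  })
  qm <- matrix(qm, nrow = nf)
  flags <- matrix(FALSE, nf, nc)
  for (c in seq_len(nc)) {
    on <- FALSE
    for (f in seq_len(nf)) {
      if (!on && qm[f, c] >= q_on) on <- TRUE
      else if (on && qm[f, c] < q_off) on <- FALSE
      flags[f, c] <- on
    }
  }
  n_bound <- rowSums(flags)
  trans <- data.frame(from = integer(0), to = integer(0), step = numeric(0))
  for (f in seq_len(nf)[-1]) {
    if (n_bound[f] != n_bound[f - 1])
      trans <- rbind(trans, data.frame(from = n_bound[f - 1],
                                       to = n_bound[f], step = steps[f]))
  }
  fp <- vapply(seq_len(nc), function(k) {
    hit <- which(n_bound >= k)
    if (length(hit)) steps[hit[1]] else NA_real_
  }, numeric(1))
  names(fp) <- paste0("reach_", seq_len(nc))
  series <- data.frame(step = steps, n_bound = n_bound)
  for (c in seq_len(nc)) series[[paste0("core", c)]] <- flags[, c]
  structure(list(series = series, transitions = trans, first_passage = fp,
                 q = qm), class = "cg_bound_series")
}

#' Single-exponential survival fit of state lifetimes
#'
#' Fits the empirical survival fraction to \eqn{P e^{-t/\tau}} by least
#' squares on the log survival curve (mirroring a straight line on a log
#' scale); the rate is k = 1/tau. Right-censored durations (runs that never
#' left the state) enter the Kaplan-Meier survival estimate but contribute
#' no event; `mle = TRUE` instead uses the censored exponential MLE
#' tau = sum(durations) / n_events.
#'
#' @param durations lifetimes in state i (reduced time units), >= 5 values.
#' @param censored logical vector (TRUE = right-censored), default none.
#' @param mle use the exponential MLE instead of the log-linear fit.
#' @return list of class `cg_rate_estimate`: tau, rate, P, r_squared,
#'   fit_residual (RMSE in log space), se_tau, n_events.
#' @export
survival_fit <- function(durations, censored = rep(FALSE, length(durations)),
                         mle = FALSE) {
  stopifnot(length(durations) == length(censored))
  if (length(durations) < 5) stop("need at least 5 durations")
  if (all(durations == durations[1]))
    stop("degenerate durations (all identical)")
  sf <- survival::survfit(survival::Surv(durations, !censored) ~ 1)
  n_events <- sum(!censored)
  if (mle) {
    tau <- sum(durations) / n_events
    return(structure(list(tau = tau, rate = 1 / tau, P = 1,
                          r_squared = NA_real_, fit_residual = NA_real_,
                          se_tau = tau / sqrt(n_events),
                          n_events = n_events, method = "mle"),
                     class = "cg_rate_estimate"))
  }
  keep <- sf$surv > 0 & sf$n.event > 0
  t <- sf$time[keep]; s <- sf$surv[keep]
  if (length(t) < 3) stop("too few event times for a log-linear fit")
  fit <- lm(log(s) ~ t)
  slope <- coef(fit)[["t"]]
  if (slope >= 0) stop("survival curve does not decay")
  tau <- -1 / slope
  res <- structure(list(tau = tau, rate = 1 / tau,
                        P = exp(coef(fit)[["(Intercept)"]]),
                        r_squared = summary(fit)$r.squared,
                        fit_residual = sqrt(mean(fit$residuals^2)),
                        se_tau = tau / sqrt(n_events),
                        n_events = n_events, method = "loglsq"),
                   class = "cg_rate_estimate")
  res
}

#' @export
print.cg_rate_estimate <- function(x, ...) {
  cat(sprintf("tau = %.4g (rate %.4g), P = %.3g, R^2 = %.4f, n = %d\n",
              x$tau, x$rate, x$P, x$r_squared, x$n_events))
  invisible(x)
}

#' Potential of mean force from a sampled coordinate
#'
#' F(r) = -kB T ln p(r), anchored so the minimum over occupied bins is 0.
#' Empty bins are reported as NA (undefined), never as 0. No Jacobian
#' correction by default; `jacobian = TRUE` divides p by r^2 first.
#'
#' @param x samples of the coordinate (A).
#' @param breaks bin breaks or a bin width (numeric scalar).
#' @param temperature K.
#' @param jacobian apply the 4 pi r^2 volume correction.
#' @return data.frame of class `cg_pmf`: r (bin centers), F (kcal/mol),
#'   count; attribute `source = "histogram"`.
#' @export
pmf_from_histogram <- function(x, breaks = 0.5, temperature = 300,
                               jacobian = FALSE) {
  if (!length(x)) stop("empty series")
  if (length(breaks) == 1)
    breaks <- seq(floor(min(x) / breaks) * breaks,
                  ceiling(max(x) / breaks) * breaks + breaks / 2, by = breaks)
  h <- hist(x, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  if (jacobian) {
    p <- ifelse(h$mids > 0, p / h$mids^2, NA)
    p <- p / sum(p, na.rm = TRUE)
  }
  F <- ifelse(p > 0, -.kB * temperature * log(p), NA)
  F <- F - min(F, na.rm = TRUE)
  out <- data.frame(r = h$mids, F = F, count = h$counts)
  attr(out, "source") <- "histogram"
  attr(out, "temperature") <- temperature
  class(out) <- c("cg_pmf", "data.frame")
  out
}

#' Weighted histogram analysis method
#'
#' Standard WHAM self-consistency for umbrella windows with harmonic
#' biases: iterates the unbiased probability p(b) and the window free
#' energies f_i until the largest change in any f_i is below `tol`
#' (kcal/mol), then returns F(r) = -kB T ln p, min-anchored.
#'
#' @param reus a `cg_reus` result, or a list of histograms
#'   (center, k, half, samples).
#' @param breaks bin width (scalar, default 0.5 A) or explicit breaks.
#' @param temperature K (defaults to the REUS temperature).
#' @param tol convergence tolerance on the window constants.
#' @param max_iter iteration cap.
#' @return `cg_pmf` data.frame with attribute `source = "wham"` and the
#'   converged window constants as attribute `f_windows`.
#' @export
wham <- function(reus, breaks = 0.5, temperature = NULL, tol = 1e-6,
                 max_iter = 10000) {
  hists <- if (inherits(reus, "cg_reus")) reus$histograms else reus
  if (is.null(temperature))
    temperature <- if (inherits(reus, "cg_reus")) reus$temperature else 300
  K <- length(hists)
  allx <- unlist(lapply(hists, `[[`, "samples"))
  if (!length(allx)) stop("empty histograms")
  if (length(breaks) == 1)
    breaks <- seq(floor(min(allx) / breaks) * breaks,
                  ceiling(max(allx) / breaks) * breaks + breaks / 2,
                  by = breaks)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  B <- length(mids)
  counts <- sapply(hists, function(h)
    hist(h$samples, breaks = breaks, plot = FALSE)$counts)
  counts <- matrix(counts, nrow = B)
  Ntot <- colSums(counts)
  if (K >= 2) {
    occ <- counts > 0
    for (w in seq_len(K - 1)) {
      if (!any(occ[, w] & occ[, w + 1]))
        stop("non-overlapping windows: gap between window ", w, " and ",
             w + 1)
    }
  }
  kT <- .kB * temperature
  bias <- sapply(seq_len(K), function(w)
    .bias_u(mids, hists[[w]]$center, hists[[w]]$k,
            isTRUE(hists[[w]]$half)))     # B x K
  bias <- matrix(bias, nrow = B)
  expb <- exp(-bias / kT)
  f <- rep(0, K)
  nb <- rowSums(counts)
  for (it in seq_len(max_iter)) {
    denom <- expb %*% (Ntot * exp(f / kT))   # B x 1
    p <- nb / as.numeric(denom)
    p[!is.finite(p)] <- 0
    fnew <- -kT * log(colSums(p * expb))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  p <- p / sum(p)
  F <- ifelse(p > 0 & nb > 0, -kT * log(p), NA)
  F <- F - min(F, na.rm = TRUE)
  out <- data.frame(r = mids, F = F, count = nb)
  attr(out, "source") <- "wham"
  attr(out, "temperature") <- temperature
  attr(out, "f_windows") <- f
  attr(out, "iterations") <- it
  class(out) <- c("cg_pmf", "data.frame")
  out
}

#' Classify linker connectivity of the bound tetramer
#'
#' With the four Cores bound to the four quarter-sites (numbered 1..4 along
#' the duplex; half-site 1 = quarters 1,2) and the TET domain forming a
#' dimer of dimers, the partition of quarter-sites induced by the TET dimer
#' partnership takes one of three canonical forms:
#' type 1 = \{\{1,3\},\{2,4\}\} (each dimer spans both half-sites,
#' parallel), type 2 = \{\{1,4\},\{2,3\}\} (crossed), type 3 =
#' \{\{1,2\},\{3,4\}\} (dimer partners on the same half-site). The label is
#' invariant under subunit relabelling.
#'
#' @param quarter_of_core integer vector of length 4: quarter-site occupied
#'   by each subunit's Core (a permutation of 1..4).
#' @param tet_partner integer vector of length 4: the TET dimer partner of
#'   each subunit (an involution without fixed points).
#' @return list of class `cg_binding_type`: type (1, 2 or 3), pairs.
#' @export
classify_connectivity <- function(quarter_of_core, tet_partner) {
  stopifnot(length(quarter_of_core) == 4, length(tet_partner) == 4)
  if (!setequal(quarter_of_core, 1:4))
    stop("quarter assignment must be a permutation of 1..4 (need a full ",
         "4-Core bound state)")
  if (any(tet_partner[tet_partner] != seq_len(4)) ||
      any(tet_partner == seq_len(4)))
    stop("tet_partner must pair the four subunits")
  pairs <- unique(t(apply(cbind(seq_len(4), tet_partner), 1, sort)))
  qpairs <- lapply(seq_len(nrow(pairs)), function(r)
    sort(quarter_of_core[pairs[r, ]]))
  key <- paste(sort(sapply(qpairs, paste, collapse = "")), collapse = "|")
  type <- switch(key,
                 "13|24" = 1L, "14|23" = 2L, "12|34" = 3L,
                 stop("quarter pairing ", key, " is not a dimer-of-dimers ",
                      "arrangement"))
  structure(list(type = type, pairs = qpairs), class = "cg_binding_type")
}

#' Frame-level connectivity typing
#'
#' Derives the quarter-site of each Core (nearest quarter-site centroid to
#' the Core centroid) and the TET partnership (from the per-subunit TET
#' inter-subunit contact lists: each subunit pairs with the subunit it
#' shares most formed TET contacts with), then calls
#' [classify_connectivity()]. Frames with fewer than 4 bound Cores are
#' reported as NA rather than an error when `strict = FALSE`.
#'
#' @param frame n x 3 coordinates.
#' @param core_beads list of 4 bead index vectors (the Cores).
#' @param quarter_beads list of 4 bead index vectors (the quarter-sites).
#' @param tet_partner length-4 involution from the topology (fixed
#'   dimer-of-dimers pairing).
#' @param strict error (TRUE) or NA (FALSE) on incomplete binding.
#' @param max_dist a Core farther than this from every quarter centroid
#'   counts as unbound (A).
#' @return `cg_binding_type` or NA.
#' @export
classify_frame <- function(frame, core_beads, quarter_beads, tet_partner,
                           strict = FALSE, max_dist = 25) {
  cent <- function(ix) colMeans(frame[ix, , drop = FALSE])
  cc <- t(sapply(core_beads, cent))
  qc <- t(sapply(quarter_beads, cent))
  d <- as.matrix(dist(rbind(cc, qc)))[1:4, 5:8]
  assign <- apply(d, 1, which.min)
  ok <- length(unique(assign)) == 4 &&
    all(d[cbind(1:4, assign)] <= max_dist)
  if (!ok) {
    if (strict) stop("fewer than 4 bound Cores in frame")
    return(NA)
  }
  classify_connectivity(assign, tet_partner)
}

#' 3-D occupancy grid of a selection centroid
#'
#' Histogram of the selection centroid over frames on a cubic voxel grid,
#' normalized to a probability per voxel (sums to 1 over occupied voxels).
#'
#' @param traj trajectory; @param selection bead indices; @param voxel
#'   voxel edge in Angstrom (> 0).
#' @return list of class `cg_occupancy_grid`: origin, voxel, dims, counts
#'   (3-D array), prob (3-D array).
#' @export
occupancy_grid <- function(traj, selection, voxel = 2) {
  stopifnot(voxel > 0)
  frames <- if (inherits(traj, "cg_trajectory")) traj$frames else traj
  nf <- dim(frames)[3]
  if (!nf) stop("empty trajectory")
  pts <- t(vapply(seq_len(nf), function(f)
    colMeans(frames[selection, , f, drop = FALSE]), numeric(3)))
  origin <- floor(apply(pts, 2, min) / voxel) * voxel
  ijk <- floor(sweep(pts, 2, origin) / voxel) + 1
  dims <- apply(ijk, 2, max)
  counts <- array(0L, dims)
  for (r in seq_len(nrow(ijk)))
    counts[ijk[r, 1], ijk[r, 2], ijk[r, 3]] <-
      counts[ijk[r, 1], ijk[r, 2], ijk[r, 3]] + 1L
  structure(list(origin = origin, voxel = voxel, dims = dims,
                 counts = counts, prob = counts / sum(counts),
                 centroids = pts),
            class = "cg_occupancy_grid")
}
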