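# alpha-helix-like compact coordinates: rise 1.5 A, 100 deg/bead, radius
# 2.3 A -> consecutive beads ~3.8 A apart, |i-j| >= 4 pairs inside 6.5 A.
.helix_coords <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1),
                          phase = 0, radius = 2.3, rise = 1.5) {
  om <- 100 * pi / 180
  t <- seq_len(n) - 1
  local <- cbind(radius * cos(om * t + phase),
                 radius * sin(om * t + phase), rise * t)
  # rotate local z onto `axis`
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  cth <- sum(z * a)
  R <- if (sum(v^2) < 1e-12) {
    if (cth > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx / (1 + cth)
  }
  sweep(local %*% t(R), 2, origin, "+")
}

# string n interior beads from a to b along a sine-arched path whose
# polyline spacing matches seg_len (keeps tether bonds near their rest
# length even when |b - a| is shorter than the contour)
.string_coords <- function(a, b, n, seg_len = 3.8, bump = NULL) {
  L <- sqrt(sum((b - a)^2))
  u <- (b - a) / L
  if (is.null(bump)) {
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- c(u[2] * ref[3] - u[3] * ref[2], u[3] * ref[1] - u[1] * ref[3],
           u[1] * ref[2] - u[2] * ref[1])
  } else {
    v <- bump - sum(bump * u) * u   # component of bump normal to the chord
  }
  v <- v / sqrt(sum(v^2))
  tfrac <- seq_len(n) / (n + 1)
  path_pts <- function(h) {
    pts <- rbind(a, sweep(outer(tfrac, b - a), 2, a, "+") +
                   h * sin(pi * tfrac) %o% v, b)
    pts
  }
  plen <- function(h) sum(sqrt(rowSums(diff(path_pts(h))^2)))
  target <- (n + 1) * seg_len
  if (plen(0) >= target) return(path_pts(0)[2:(n + 1), , drop = FALSE])
  h <- stats::uniroot(function(h) plen(h) - target, c(0, target))$root
  path_pts(h)[2:(n + 1), , drop = FALSE]
}

# damped (zero-temperature) dynamics to relieve residual construction
# clashes; deterministic (no thermal noise)
.relax_coords <- function(topo, coords, ff, steps = c(2000, 3000),
                          dt = c(0.01, 0.05)) {
  sys <- build_sim_system(topo, ff)
  st <- sim_state(coords)
  for (g in seq_along(steps)) {
    lp <- langevin_params(dt = dt[g], gamma = 1, temperature = 0, seed = 1)
    st <- langevin_step(st, sys, lp, steps[g])
    st$velocities[] <- 0
  }
  st$coords
}

# cross-interface Go contacts between two bead sets at a reference pose
.interface_contacts <- function(coords, setA, setB, cutoff, eps, cat) {
  pairs <- list()
  for (i in setA) {
    d <- sqrt(colSums((t(coords[setB, , drop = FALSE]) - coords[i, ])^2))
    hit <- setB[d <= cutoff]
    for (j in hit)
      pairs[[length(pairs) + 1]] <- data.frame(
        i = min(i, j), j = max(i, j),
        r0 = sqrt(sum((coords[i, ] - coords[j, ])^2)), eps = eps, cat = cat)
  }
  if (!length(pairs)) return(empty_contacts())
  df <- do.call(rbind, pairs)
  cg_contacts(df$i, df$j, df$r0, df$eps, df$cat)
}

#' Synthetic test systems
#'
#' Seeded, reproducible stand-ins for the p53/DNA system, emulating the
#' statistical structure the analysis assumes: compact folded Go domains,
#' a positively charged disordered tail (CTD analog), straight duplex DNA
#' with an annotated RE, and (for the bound kinds) a docked reference pose
#' defining Core--RE (and Core--Core, TET--TET) contacts.
#'
#' Kinds:
#' \describe{
#' \item{free_dna}{a duplex with an RE annotation and no protein.}
#' \item{mini_core_dna}{one folded mini-Core with a charged tail docked on
#'   half-site 1 of a duplex; Core--RE contacts from the docked pose.}
#' \item{tetramer_toy}{four Core--linker--TET subunits whose TET segments
#'   form a dimer of dimers (partners 1-2 and 3-4); Cores docked on the
#'   four quarter-sites at the reference pose, Core--Core contacts across
#'   the longitudinally adjacent pair.}
#' }
#'
#' @param kind one of `"mini_core_dna"`, `"tetramer_toy"`, `"free_dna"`.
#' @param params list of overrides: `dna_bp`, `re_start`, `spacer`,
#'   `core_n`, `tail_n`, `linker_n`, `tet_n`, `cross_cutoff`,
#'   `displace` (A, initial Core displacement for `start = "unbound"`).
#' @param seed integer seed (placement jitter only; the construction is
#'   otherwise deterministic).
#' @param ff force field.
#' @param start `"reference"` (docked pose) or `"unbound"` (Cores displaced
#'   away from the DNA, tetramer_toy only).
#' @return list of class `cg_fixture`: `topology` (contacts included),
#'   `coords`, `re`, and for the bound kinds `core_beads`,
#'   `core_contacts` (per-Core Core--RE sublists), `quarter_beads`,
#'   `tet_partner`, `dna_beads`, `protein_beads`.
#' @export
make_toy_fixture <- function(kind = c("mini_core_dna", "tetramer_toy",
                                      "free_dna"),
                             params = list(), seed = 1,
                             ff = default_forcefield(),
                             start = c("reference", "unbound")) {
  kind <- match.arg(kind)
  start <- match.arg(start)
  p <- modifyList(list(dna_bp = 30, re_start = 11, spacer = 0,
                       core_n = if (kind == "tetramer_toy") 10 else 24,
                       tail_n = 8, linker_n = 10, tet_n = 4,
                       cross_cutoff = 10, displace = 15), params)
  if (p$core_n < 4 || p$dna_bp < 2) stop("degenerate sizes")
  set.seed(seed)
  if (kind == "tetramer_toy" && p$dna_bp < p$re_start + 19 + p$spacer)
    stop("duplex too short for the RE")

  seqd <- re_sequence(p$dna_bp, p$re_start, p$spacer)
  re <- annotate_re(p$dna_bp, p$re_start, p$spacer, sequence = seqd)
  dna <- build_dna_topology(seqd, duplex = TRUE, ff = ff, re = re)
  g <- .bdna_geom

  if (kind == "free_dna") {
    dna$coords <- dna$coords
    fx <- structure(list(topology = dna, coords = dna$coords, re = re,
                         dna_beads = seq_len(n_beads(dna)), kind = kind,
                         seed = seed, params = p),
                    class = "cg_fixture")
    return(fx)
  }

  quarter_z <- vapply(re$quarters, function(q) mean(q - 1) * g$rise,
                      numeric(1))
  # bead indices of each quarter-site footprint (both strands)
  quarter_beads <- lapply(re$quarters, function(q) {
    b <- dna$beads
    bp <- ifelse(b$chain == 1, b$resid, p$dna_bp + 1 - b$resid)
    which(bp >= q[1] & bp <= q[2])
  })

  if (kind == "mini_core_dna") {
    nprot <- p$core_n + p$tail_n
    aa <- rep("A", nprot)
    aa[seq(1, p$core_n, by = 4)] <- "K"          # DNA-facing positive patch
    aa[p$core_n + seq_len(p$tail_n)] <-
      rep(c("K", "A"), length.out = p$tail_n)    # net-positive tail
    dmap <- domain_map(c("Core", "CTD"), c(1, p$core_n + 1),
                       c(p$core_n, nprot), folded = c(TRUE, FALSE))
    zc <- mean(unlist(re$half_site1) - 1) * g$rise
    core_xy <- c(14.5, 0)
    core_coords <- .helix_coords(p$core_n,
                                 origin = c(core_xy, zc - 0.75 * p$core_n *
                                              1.5 / 2),
                                 axis = c(0, 0, 1))
    prot <- build_protein_topology(paste(aa, collapse = ""), dmap,
                                   native_coords = list(Core = core_coords),
                                   ff = ff, subunit = 1L)
    # tail extends away from the DNA
    for (i in (p$core_n + 1):nprot)
      prot$coords[i, ] <- prot$coords[p$core_n, ] +
        c(3.8 * (i - p$core_n), 0, 0)
    sys_topo <- combine_topologies(list(dna, prot),
                                   coords = list(dna$coords, prot$coords))
    off <- n_beads(dna)
    core_idx <- off + seq_len(p$core_n)
    re_beads <- unique(c(quarter_beads[[1]], quarter_beads[[2]]))
    cre <- .interface_contacts(sys_topo$coords, core_idx, re_beads,
                               p$cross_cutoff, ff$eps_core_re, "core_re")
    if (!nrow(cre)) stop("docked pose produced no Core-RE contacts")
    sys_topo$contacts <- rbind_contacts(sys_topo$contacts, cre)
    fx <- structure(list(topology = sys_topo, coords = sys_topo$coords,
                         re = re, dna_beads = seq_len(off),
                         protein_beads = off + seq_len(nprot),
                         core_beads = list(core_idx),
                         core_contacts = list(cre),
                         quarter_beads = quarter_beads, kind = kind,
                         seed = seed, params = p),
                    class = "cg_fixture")
    return(fx)
  }

  # --- tetramer_toy ---------------------------------------------------------
  nsub <- p$core_n + p$linker_n + p$tet_n
  hub <- c(0, 20, mean(quarter_z))
  # Cores on alternating DNA faces (+x, -x, -x, +x): the longitudinally
  # adjacent pair (quarters 2, 3) shares a face and forms Core-Core contacts
  azim <- c(1, -1, -1, 1)
  tet_partner <- c(2L, 1L, 4L, 3L)
  # TET bundle above the duplex: partner segments 5.2 A apart in x
  # (contacts form at <= 6.5 A), the two dimers stacked 10 A apart in z
  # (no cross-dimer contacts); each subunit's segment sits on its own
  # DNA face so the linkers never cross the duplex
  tet_x <- 2.6 * azim
  tet_dz <- c(-5, -5, 5, 5)
  subunits <- list(); coords_list <- list()
  dmap <- domain_map(c("Core", "Linker", "TET"),
                     c(1, p$core_n + 1, p$core_n + p$linker_n + 1),
                     c(p$core_n, p$core_n + p$linker_n, nsub),
                     folded = c(TRUE, FALSE, TRUE),
                     linker = c(FALSE, TRUE, FALSE))
  for (s in 1:4) {
    aa <- rep("A", nsub)
    aa[seq(1, p$core_n, by = 4)] <- "K"
    core_origin <- c(15 * azim[s], 0,
                     quarter_z[s] - 1.5 * (p$core_n - 1) / 2)
    core_coords <- .helix_coords(p$core_n, origin = core_origin,
                                 axis = c(0, 0, 1), phase = pi * (s %% 2))
    tet_origin <- hub + c(tet_x[s], 0, tet_dz[s] - 1.5 * (p$tet_n - 1) / 2)
    tet_coords <- .helix_coords(p$tet_n, origin = tet_origin,
                                axis = c(0, 0, 1), radius = 1.0)
    prot <- build_protein_topology(paste(aa, collapse = ""), dmap,
                                   native_coords = list(Core = core_coords,
                                                        TET = tet_coords),
                                   ff = ff, subunit = s)
    # linker strung Core end -> TET start at near-rest bond lengths,
    # arched radially away from the DNA axis
    a <- core_coords[p$core_n, ]; b <- tet_coords[1, ]
    mid <- (a + b) / 2
    bump <- c(mid[1], mid[2], 0)
    if (sum(bump^2) < 1) bump <- c(azim[s], 1, 0)
    prot$coords[p$core_n + seq_len(p$linker_n), ] <-
      .string_coords(a, b, p$linker_n, seg_len = ff$bond_r0_disordered,
                     bump = bump) +
      matrix(runif(3 * p$linker_n, -0.2, 0.2), p$linker_n, 3)
    subunits[[s]] <- prot
    coords_list[[s]] <- prot$coords
  }
  all_parts <- c(list(dna), subunits)
  all_coords <- c(list(dna$coords), coords_list)
  topo <- combine_topologies(all_parts, coords = all_coords)
  off <- n_beads(dna)
  core_beads <- lapply(1:4, function(s) off + (s - 1) * nsub + seq_len(p$core_n))
  tet_beads <- lapply(1:4, function(s)
    off + (s - 1) * nsub + p$core_n + p$linker_n + seq_len(p$tet_n))
  coords <- topo$coords
  # Core-RE contacts, per core on its own quarter-site
  core_contacts <- list()
  extra <- list()
  for (s in 1:4) {
    cre <- .interface_contacts(coords, core_beads[[s]], quarter_beads[[s]],
                               p$cross_cutoff, ff$eps_core_re, "core_re")
    if (!nrow(cre)) stop("core ", s, " has no Core-RE contacts at reference")
    core_contacts[[s]] <- cre
    extra[[length(extra) + 1]] <- as.data.frame(cre)
  }
  # TET dimer contacts (partners only)
  for (s in c(1, 3)) {
    tt <- .interface_contacts(coords, tet_beads[[s]],
                              tet_beads[[tet_partner[s]]], 6.5,
                              ff$eps_intra * 2, "intra")
    if (!nrow(tt)) stop("TET partners ", s, " share no contacts")
    extra[[length(extra) + 1]] <- as.data.frame(tt)
  }
  # Core-Core contacts across the longitudinally adjacent pair (quarters 2,3)
  ccc <- .interface_contacts(coords, core_beads[[2]], core_beads[[3]], 9,
                             ff$eps_core_core, "core_core")
  if (nrow(ccc)) extra[[length(extra) + 1]] <- as.data.frame(ccc)
  # intra-linker pair terms (uniform strength), r0 from the reference pose
  for (s in 1:4) {
    lbeads <- off + (s - 1) * nsub + p$core_n + seq_len(p$linker_n)
    ii <- lbeads[seq(1, p$linker_n - 4, by = 2)]
    jj <- ii + 4L
    r0 <- sqrt(rowSums((coords[ii, , drop = FALSE] -
                          coords[jj, , drop = FALSE])^2))
    extra[[length(extra) + 1]] <- data.frame(i = ii, j = jj, r0 = r0,
                                             eps = ff$eps_linker,
                                             cat = "linker")
  }
  ex <- do.call(rbind, extra)
  topo$contacts <- rbind_contacts(topo$contacts,
                                  cg_contacts(ex$i, ex$j, ex$r0, ex$eps,
                                              ex$cat))
  if (start == "unbound") {
    # push each Core (and re-string its linker) radially off the DNA
    for (s in 1:4) {
      shift <- c(azim[s] * p$displace, 0, 0) +
        c(0, runif(1, -3, 3), runif(1, -3, 3))
      coords[core_beads[[s]], ] <-
        sweep(coords[core_beads[[s]], ], 2, shift, "+")
      a <- coords[core_beads[[s]][p$core_n], ]
      b <- coords[tet_beads[[s]][1], ]
      mid <- (a + b) / 2
      lbeads <- off + (s - 1) * nsub + p$core_n + seq_len(p$linker_n)
      coords[lbeads, ] <- .string_coords(a, b, p$linker_n, seg_len = 3.8,
                                         bump = c(mid[1], mid[2], 0)) +
        matrix(runif(3 * p$linker_n, -0.2, 0.2), p$linker_n, 3)
    }
    topo$coords <- coords
  }
  coords <- .relax_coords(topo, coords, ff)
  topo$coords <- coords
  structure(list(topology = topo, coords = coords, re = re,
                 dna_beads = seq_len(off),
                 protein_beads = off + seq_len(4 * nsub),
                 core_beads = core_beads, tet_beads = tet_beads,
                 core_contacts = core_contacts,
                 quarter_beads = quarter_beads,
                 tet_partner = tet_partner, kind = kind, seed = seed,
                 params = p),
            class = "cg_fixture")
}

#' Fix the two duplex ends of a fixture's DNA
#'
#' Marks the first and last base-pair beads of both strands as fixed,
#' mirroring the production constraint on the dsDNA ends.
#' @param fixture a `cg_fixture`.
#' @return the fixture with its topology's fixed mask updated.
#' @export
fix_dna_ends <- function(fixture) {
  topo <- fixture$topology
  b <- topo$beads
  is_dna <- seq_len(nrow(b)) %in% fixture$dna_beads
  ends <- is_dna & (b$resid == 1 | b$resid == max(b$resid[is_dna]))
  topo$fixed[ends] <- TRUE
  fixture$topology <- topo
  fixture
}

#' Sequential-binding demonstration runs
#'
#' Starts the tetramer toy from the displaced (unbound) pose and runs
#' Langevin dynamics, tracking the per-Core Core--RE Q-scores. A run is a
#' "sequential" success when the bound-core count reaches 4 and its
#' transition sequence after the last visit to 0 is non-decreasing.
#'
#' @param n_runs number of independent seeded runs.
#' @param nsteps steps per run; @param seed master seed;
#' @param params fixture parameter overrides; @param ff force field;
#' @param stride frame interval for the Q-score analysis.
#' @param q_on,q_off bound-core hysteresis thresholds.
#' @return data.frame: run, reached4, monotone, success, n_transitions,
#'   final_n_bound.
#' @export
run_binding_demo <- function(n_runs = 10, nsteps = 800000, seed = 1,
                             params = list(), ff = default_forcefield(),
                             stride = 2000, q_on = 0.5, q_off = 0.35) {
  out <- list()
  for (r in seq_len(n_runs)) {
    row <- tryCatch({
      fx <- make_toy_fixture("tetramer_toy", params = params,
                             seed = seed + r, ff = ff, start = "unbound")
      fx <- fix_dna_ends(fx)
      sys <- build_sim_system(fx$topology, ff)
      lp <- langevin_params(dt = 0.1, gamma = 0.02,
                            temperature = ff$elec$temperature,
                            seed = seed * 1000 + r)
      traj <- run_simulation(sys, fx$coords, lp, nsteps, stride = stride)
      bs <- assign_bound_cores(traj, fx$core_contacts, q_on = q_on,
                               q_off = q_off)
      nb <- bs$series$n_bound
      reached4 <- any(nb == 4)
      monotone <- monotone_since_last_zero(bs$transitions)
      data.frame(run = r, reached4 = reached4, monotone = monotone,
                 success = reached4 && monotone,
                 n_transitions = nrow(bs$transitions),
                 final_n_bound = tail(nb, 1))
    }, error = function(e) {
      warning("run ", r, " failed: ", conditionMessage(e))
      data.frame(run = r, reached4 = FALSE, monotone = FALSE,
                 success = FALSE, n_transitions = NA_integer_,
                 final_n_bound = NA_integer_)
    })
    out[[r]] <- row
  }
  do.call(rbind, out)
}

#' Is the transition record non-decreasing after its last visit to zero?
#' @param transitions data.frame(from, to, step) from
#'   [assign_bound_cores()].
#' @export
monotone_since_last_zero <- function(transitions) {
  if (!nrow(transitions)) return(FALSE)
  zero <- which(transitions$to == 0)
  start <- if (length(zero)) max(zero) + 1 else 1
  if (start > nrow(transitions)) return(FALSE)
  seg <- transitions[start:nrow(transitions), ]
  all(seg$to > seg$from)
}
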