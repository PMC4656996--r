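# category name -> C++ slice index (0-based); keep in sync with src/cg_core.cpp
.cat_names <- c("local_folded", "local_disordered", "contacts_intra",
                "contacts_CoreRE", "contacts_CoreCore", "linker_pairs",
                "dna_bonded", "dna_stack_pair", "electrostatic",
                "excluded_volume", "bias", "container")

.bond_cat <- c(folded = 0L, disordered = 1L, dna = 6L)
.con_cat <- c(intra = 2L, core_re = 3L, core_core = 4L, linker = 5L,
              dna_stack = 7L, dna_pair = 7L)

# bonded pairs up to 3 bonds apart (1-2, 1-3, 1-4) -- excluded from EV and DH
.bonded_exclusions <- function(topo) {
  n <- n_beads(topo)
  adj <- vector("list", n)
  for (t in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds$i[t]; j <- topo$bonds$j[t]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  keys <- new.env(hash = TRUE)
  out_i <- integer(0); out_j <- integer(0)
  add <- function(a, b) {
    if (a == b) return()
    lo <- min(a, b); hi <- max(a, b)
    k <- paste0(lo, "_", hi)
    if (is.null(keys[[k]])) {
      keys[[k]] <- TRUE
      out_i <<- c(out_i, lo); out_j <<- c(out_j, hi)
    }
  }
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      add(i, j)
      for (k in adj[[j]]) {
        add(i, k)
        for (l in adj[[k]]) add(i, l)
      }
    }
  }
  list(i = out_i, j = out_j)
}

#' Flatten topology + force field into a simulation system
#'
#' Precomputes everything the compute kernels need: per-bead charges, radii
#' (by bead kind from the force-field radii table), masses, bonded-term
#' arrays with category codes, contact arrays, statistical tables, the Debye
#' length for the current temperature/salt, non-bonded exclusion lists
#' (pairs within 3 bonds; contact pairs are additionally excluded from
#' excluded volume), optional spherical container and optional
#' centroid-distance bias/reaction-coordinate groups.
#'
#' @param topo `cg_topology`.
#' @param ff `cg_forcefield`.
#' @param container NULL or `list(center =, radius =, k = )`.
#' @param bias NULL or `list(groupA =, groupB =, k =, r0 =, half = TRUE)`;
#'   with `k = 0` the groups only define a recorded reaction coordinate.
#' @return list of class `cg_system` consumed by [total_energy()],
#'   [run_simulation()] and [run_reus()].
#' @export
build_sim_system <- function(topo, ff = default_forcefield(),
                             container = NULL, bias = NULL) {
  validate_topology(topo)
  b <- topo$beads
  n <- nrow(b)
  radii <- ff$ev$radii[b$kind]
  excl <- .bonded_exclusions(topo)
  # contact pairs (incl. stacking/pairing) are handled by their own term
  con <- topo$contacts
  ev_i <- c(excl$i, con$i); ev_j <- c(excl$j, con$j)
  lam <- debye_length(ff$elec$temperature, ff$elec$salt, ff$elec$dielectric)
  ang <- topo$angles; dih <- topo$dihedrals
  sys <- list(
    charge = as.numeric(b$charge),
    radius = as.numeric(radii),
    mass = rep(ff$mass, n),
    fixed = as.integer(topo$fixed),
    b_i = topo$bonds$i - 1L, b_j = topo$bonds$j - 1L,
    b_cat = unname(.bond_cat[topo$bonds$cat]),
    b_k = topo$bonds$kf, b_r0 = topo$bonds$r0,
    a_i = ang$i - 1L, a_j = ang$j - 1L, a_k = ang$k - 1L,
    a_type = as.integer(ang$type == "table"),
    a_cls = as.integer(ang$class) - 1L,
    a_cat = unname(.bond_cat[ang$cat]),
    a_kf = ang$kf, a_th0 = ifelse(is.na(ang$th0), 0, ang$th0),
    d_i = dih$i - 1L, d_j = dih$j - 1L, d_k = dih$k - 1L, d_l = dih$l - 1L,
    d_type = as.integer(dih$type == "table"),
    d_cls = as.integer(dih$class) - 1L,
    d_cat = unname(.bond_cat[dih$cat]),
    d_kf = dih$kf, d_phi0 = ifelse(is.na(dih$phi0), 0, dih$phi0),
    c_i = con$i - 1L, c_j = con$j - 1L,
    c_cat = unname(.con_cat[con$cat]),
    c_r0 = con$r0, c_eps = con$eps,
    ang_tab = ff$tables$angle, dih_tab = ff$tables$dihedral,
    ev_eps = ff$ev$eps,
    elec_cutoff = ff$elec$cutoff,
    lB = .kC / ff$elec$dielectric,
    lambdaD = lam,
    excl_ev_i = ev_i - 1L, excl_ev_j = ev_j - 1L,
    excl_dh_i = excl$i - 1L, excl_dh_j = excl$j - 1L,
    container = if (is.null(container)) list(has = FALSE) else
      list(has = TRUE, center = as.numeric(container$center),
           radius = container$radius,
           k = if (is.null(container$k)) 10 else container$k),
    bias = if (is.null(bias)) list(has = FALSE, groupA = integer(0),
                                   groupB = integer(0)) else
      list(has = TRUE, k = if (is.null(bias$k)) 0 else bias$k,
           r0 = if (is.null(bias$r0)) 0 else bias$r0,
           half = if (is.null(bias$half)) TRUE else bias$half,
           groupA = as.integer(bias$groupA) - 1L,
           groupB = as.integer(bias$groupB) - 1L)
  )
  sys$n <- n
  sys$temperature <- ff$elec$temperature
  sys$topology <- topo
  class(sys) <- "cg_system"
  sys
}

#' Total energy, per-category breakdown and forces
#'
#' Evaluates the composite potential: local folded/disordered terms, Go
#' contacts by category, DNA bonded and stacking/pairing terms, screened
#' electrostatics (Debye-Hueckel, 50 A truncated-shifted), excluded volume,
#' container wall and bias. Forces are analytic for every term.
#'
#' @param sys `cg_system` from [build_sim_system()].
#' @param coords n x 3 matrix in Angstrom.
#' @param forces return the force matrix too.
#' @return list of class `cg_energy`: `breakdown` (named numeric, kcal/mol),
#'   `total`, optionally `forces` (kcal/mol/A), and `rc` (the reaction
#'   coordinate if bias groups are defined).
#' @export
total_energy <- function(sys, coords, forces = FALSE) {
  stopifnot(inherits(sys, "cg_system"), nrow(coords) == sys$n)
  out <- cpp_energy_forces(sys, coords)
  res <- list(breakdown = out$breakdown, total = out$total, rc = out$rc)
  if (forces) res$forces <- out$forces
  class(res) <- "cg_energy"
  res
}

#' @export
print.cg_energy <- function(x, ...) {
  nz <- x$breakdown[x$breakdown != 0]
  cat("total energy:", format(x$total, digits = 8), "kcal/mol\n")
  for (nm in names(nz)) cat(sprintf("  %-18s %12.6f\n", nm, nz[[nm]]))
  invisible(x)
}
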