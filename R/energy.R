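#' Go 12-10 contact energy
#'
#' \eqn{U(r) = \epsilon\,[5 (r_0/r)^{12} - 6 (r_0/r)^{10}]}: single minimum
#' of depth \eqn{-\epsilon} at \eqn{r = r_0}, vanishing at large r. Below
#' \eqn{0.5 r_0} the energy is clamped at its value there (overflow guard;
#' the system kernels apply the same clamp).
#'
#' @param r distance(s), Angstrom (> 0).
#' @param r0 native distance, Angstrom.
#' @param eps well depth, kcal/mol (>= 0).
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
contact_energy <- function(r, r0, eps = 1) {
  stopifnot(all(r > 0), all(r0 > 0), all(eps >= 0))
  rc <- pmax(r, 0.5 * r0)
  s <- r0 / rc
  eps * (5 * s^12 - 6 * s^10)
}

#' Debye-Hueckel screened electrostatic energy
#'
#' \eqn{U(r) = q_i q_j k_C / (\epsilon_r r)\, e^{-r/\lambda_D}} with the
#' Debye length from [debye_length()]. This is the untruncated pair form;
#' inside simulations the interaction is truncated and shifted at the
#' force-field cutoff (50 A by default).
#'
#' @param r distance(s) in Angstrom (> 0).
#' @param qi,qj charges in units of e.
#' @param temperature K; @param salt mol/L; @param dielectric relative.
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
debye_huckel_energy <- function(r, qi, qj, temperature = 300, salt = 0.21,
                                dielectric = 78) {
  stopifnot(all(r > 0), salt > 0)
  lam <- debye_length(temperature, salt, dielectric)
  qi * qj * .kC / (dielectric * r) * exp(-r / lam)
}

#' Excluded-volume energy
#'
#' \eqn{U(r) = \epsilon_{ev} (\sigma/r)^{12}}, truncated and shifted to zero
#' at \eqn{r = 2\sigma} (the constant \eqn{\epsilon_{ev} 2^{-12}} is
#' subtracted inside the cutoff). Monotone decreasing on (0, 2 sigma).
#'
#' @param r distance(s), Angstrom (> 0).
#' @param sigma contact diameter (sum of bead radii), Angstrom.
#' @param eps_ev strength, kcal/mol (default 0.2).
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
excluded_volume_energy <- function(r, sigma, eps_ev = 0.2) {
  stopifnot(all(r > 0), sigma > 0)
  rc <- pmax(r, 0.4 * sigma)
  u <- eps_ev * (sigma / rc)^12 - eps_ev * 0.5^12
  ifelse(r >= 2 * sigma, 0, u)
}

# --- statistical local terms (R reference path, mirrors the C++ kernel) ----

# Catmull-Rom on a uniform grid; same tangent/end conventions as the kernel.
.catmull <- function(y, x0, dx, periodic, x) {
  ng <- length(y)
  if (periodic) {
    u <- (x - x0) %% (ng * dx)
    k0 <- pmin(floor(u / dx), ng - 1)
    t <- u / dx - k0
    Y <- function(k) y[((k %% ng) + ng) %% ng + 1]
  } else {
    u <- pmin(pmax((x - x0) / dx, 0), ng - 1 - 1e-12)
    k0 <- floor(u)
    t <- u - k0
    Y <- function(k) y[pmin(pmax(k, 0), ng - 1) + 1]
  }
  ym1 <- Y(k0 - 1); y0 <- Y(k0); y1 <- Y(k0 + 1); y2 <- Y(k0 + 2)
  m0 <- ifelse(!periodic & k0 == 0, y1 - y0, 0.5 * (y1 - ym1))
  m1 <- ifelse(!periodic & k0 >= ng - 2, y1 - y0, 0.5 * (y2 - y0))
  h00 <- 2 * t^3 - 3 * t^2 + 1; h10 <- t^3 - 2 * t^2 + t
  h01 <- -2 * t^3 + 3 * t^2; h11 <- t^3 - t^2
  h00 * y0 + h10 * m0 + h01 * y1 + h11 * m1
}

#' Statistical local energy of the disordered regions
#'
#' Sum of table-interpolated virtual-bond-angle and virtual-dihedral
#' energies over all disordered-region triples/quadruples in the topology.
#' The dihedral table is periodic; interpolation is C1-continuous. This R
#' implementation is the reference for the compiled kernel.
#'
#' @param topo `cg_topology`; @param coords n x 3 matrix.
#' @param tables as from [default_local_tables()].
#' @return energy in kcal/mol.
#' @export
statistical_local_energy <- function(topo, coords,
                                     tables = default_local_tables()) {
  e <- 0
  ang <- topo$angles[topo$angles$type == "table", , drop = FALSE]
  ng_a <- ncol(tables$angle)
  for (t in seq_len(nrow(ang))) {
    th <- .angle_of(coords, c(ang$i[t], ang$j[t], ang$k[t]))
    if (th < 0 || th > pi) stop("angle outside [0, pi]")
    cls <- ang$class[t]
    if (cls > nrow(tables$angle)) stop("missing angle table entry")
    e <- e + ang$kf[t] *
      .catmull(tables$angle[cls, ], 0, pi / (ng_a - 1), FALSE, th)
  }
  dih <- topo$dihedrals[topo$dihedrals$type == "table", , drop = FALSE]
  ng_d <- ncol(tables$dihedral)
  for (t in seq_len(nrow(dih))) {
    ph <- .dihedral_of(coords, c(dih$i[t], dih$j[t], dih$k[t], dih$l[t]))
    cls <- dih$class[t]
    if (cls > nrow(tables$dihedral)) stop("missing dihedral table entry")
    e <- e + dih$kf[t] *
      .catmull(tables$dihedral[cls, ], -pi, 2 * pi / ng_d, TRUE, ph)
  }
  e
}

#' Linker-region energy: pairwise Go terms plus statistical local terms
#'
#' The linker carries the same statistical local potential as the other
#' disordered regions plus designated pairwise contact-form terms with
#' per-pair strengths (category `linker` in the contact list; uniform
#' strength by default, per-pair values via the contact list).
#'
#' @param topo `cg_topology` with linker beads labelled.
#' @param coords n x 3 matrix.
#' @param tables statistical tables.
#' @param eps_scale multiply all linker pair strengths (for sensitivity
#'   checks).
#' @return list(pairs =, local =, total =) in kcal/mol.
#' @export
linker_pair_energy <- function(topo, coords,
                               tables = default_local_tables(),
                               eps_scale = 1) {
  lk <- topo$contacts[topo$contacts$cat == "linker", , drop = FALSE]
  if (!any(topo$beads$domain == "Linker") && nrow(lk) == 0 &&
      !any(topo$beads$domain == "linker"))
    stop("topology has no linker labels or linker pairs")
  ep <- 0
  for (t in seq_len(nrow(lk))) {
    r <- sqrt(sum((coords[lk$i[t], ] - coords[lk$j[t], ])^2))
    ep <- ep + contact_energy(r, lk$r0[t], eps_scale * lk$eps[t])
  }
  lin_beads <- which(topo$beads$domain %in% c("Linker", "linker"))
  sub <- topo
  keep_a <- topo$angles$type == "table" &
    topo$angles$i %in% lin_beads & topo$angles$k %in% lin_beads
  keep_d <- topo$dihedrals$type == "table" &
    topo$dihedrals$i %in% lin_beads & topo$dihedrals$l %in% lin_beads
  sub$angles <- topo$angles[keep_a, , drop = FALSE]
  sub$dihedrals <- topo$dihedrals[keep_d, , drop = FALSE]
  el <- statistical_local_energy(sub, coords, tables)
  list(pairs = ep, local = el, total = ep + el)
}

#' DNA energy slice
#'
#' Bonded (bonds/angles/dihedrals at B-form native values), intra-strand
#' stacking and Watson-Crick pairing contacts, and phosphate-phosphate
#' electrostatics for a DNA topology. A simplified 3SPN-style model: no
#' solvation term, Debye-Hueckel only.
#'
#' @param topo DNA `cg_topology`; @param coords matrix; @param ff force field.
#' @return named numeric: dna_bonded, dna_stack_pair, electrostatic,
#'   excluded_volume, total.
#' @export
dna_energy <- function(topo, coords, ff = default_forcefield()) {
  kinds <- topo$beads$kind
  if (any(!kinds %in% c("P", "S", "B")))
    stop("dna_energy expects a pure DNA topology")
  bad <- topo$contacts$cat %in% c("dna_stack", "dna_pair") &
    (kinds[topo$contacts$i] != "B" | kinds[topo$contacts$j] != "B")
  if (any(bad)) stop("stacking/pairing list references non-base beads")
  sys <- build_sim_system(topo, ff)
  e <- total_energy(sys, coords)
  out <- e$breakdown[c("dna_bonded", "dna_stack_pair", "electrostatic",
                       "excluded_volume")]
  c(out, total = sum(out))
}
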