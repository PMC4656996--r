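#' Default statistical local-potential tables
#'
#' Generic worm-like local propensity for disordered regions, tabulated on
#' uniform grids and evaluated with C1-continuous Catmull-Rom interpolation
#' (periodic for the dihedral table). One residue class ("generic") is
#' shipped; users may supply their own per-class tables with the same grid
#' layout.
#'
#' @param n_angle,n_dihedral grid sizes. Angle grid spans \[0, pi\] inclusive;
#'   dihedral grid spans \[-pi, pi) with periodic wrap.
#' @return list with `angle` and `dihedral` matrices (class x grid point),
#'   in kcal/mol.
#' @export
default_local_tables <- function(n_angle = 37, n_dihedral = 36) {
  th <- seq(0, pi, length.out = n_angle)
  # broad minimum near the typical Calpha virtual bond angle (~115 deg)
  ang <- 3.0 * (th - 2.0)^2
  ph <- seq(-pi, pi, length.out = n_dihedral + 1)[1:n_dihedral]
  # mild trans preference, sub-kcal/mol barriers
  dih <- 0.30 * (1 + cos(ph)) + 0.10 * (1 + cos(2 * ph))
  list(angle = matrix(ang, nrow = 1, dimnames = list("generic", NULL)),
       dihedral = matrix(dih, nrow = 1, dimnames = list("generic", NULL)))
}

#' Default composite force field
#'
#' All strengths in kcal/mol, lengths in Angstrom. The recognition strengths
#' (`eps_core_re`, `eps_core_core`, `eps_linker`) are free parameters; the
#' defaults keep the bundled mini Core--RE fixture stably bound at 300 K.
#' `eps_bp_AT < eps_bp_GC` by construction. The Debye length is recomputed
#' from temperature/salt by [build_sim_system()] whenever either changes.
#'
#' @param temperature K (default 300).
#' @param salt monovalent salt, mol/L (default 0.21).
#' @param ... overrides for any top-level entry.
#' @return list of class `cg_forcefield`.
#' @export
default_forcefield <- function(temperature = 300, salt = 0.21, ...) {
  ff <- list(
    k_bond = 100, k_angle = 20, k_dihedral = 1,
    bond_r0_disordered = 3.8,
    dna = list(k_bond = 60, k_angle = 25, k_dihedral = 2,
               eps_stack = 1.2, eps_bp_AT = 1.0, eps_bp_GC = 1.5),
    eps_intra = 0.3, eps_core_re = 1.2, eps_core_core = 0.5,
    eps_linker = 0.2,
    ev = list(eps = 0.2, radii = c(CA = 2.0, P = 1.9, S = 2.1, B = 1.8)),
    elec = list(temperature = temperature, salt = salt, dielectric = 78,
                cutoff = 50),
    contact_cutoff = 6.5, contact_min_seq_sep = 4,
    mass = 50,
    tables = default_local_tables()
  )
  over <- list(...)
  if (length(over)) ff <- modifyList(ff, over)
  class(ff) <- "cg_forcefield"
  ff
}

#' @export
print.cg_forcefield <- function(x, ...) {
  lam <- debye_length(x$elec$temperature, x$elec$salt, x$elec$dielectric)
  cat("cg_forcefield: T =", x$elec$temperature, "K, salt =", x$elec$salt,
      "M, lambda_D =", round(lam, 3), "A\n")
  cat("  eps: intra", x$eps_intra, "| Core-RE", x$eps_core_re,
      "| Core-Core", x$eps_core_core, "| linker", x$eps_linker,
      "| EV", x$ev$eps, "\n")
  invisible(x)
}
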