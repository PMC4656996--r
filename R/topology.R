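#' @useDynLib p53cg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dist setNames coef lm sd runif rexp optimize rnorm
#' @importFrom graphics hist
#' @importFrom utils head tail modifyList
NULL

# amino-acid charge rule: +1 Lys/His/Arg, -1 Asp/Glu, 0 otherwise
.aa_charge <- function(aa) {
  ifelse(aa %in% c("K", "H", "R"), 1, ifelse(aa %in% c("D", "E"), -1, 0))
}

#' Construct an empty coarse-grained topology
#'
#' A `cg_topology` bundles the bead table, bonded terms (with native values),
#' structure-based contact list, fixed-bead mask and optional response-element
#' annotation. Beads are 1-based; all bonded index tuples refer to rows of
#' `beads`.
#'
#' @param beads data.frame with columns chain, resid, kind (CA/P/S/B), name,
#'   charge (e), domain, subunit.
#' @param bonds,angles,dihedrals bonded-term tables (may be empty).
#' @param contacts a `cg_contacts` data.frame (i, j, r0, eps, cat).
#' @param fixed logical mask, one entry per bead.
#' @param re optional RE annotation (see [annotate_re()]).
#' @return object of class `cg_topology`.
#' @export
cg_topology <- function(beads,
                        bonds = empty_bonds(), angles = empty_angles(),
                        dihedrals = empty_dihedrals(),
                        contacts = empty_contacts(),
                        fixed = rep(FALSE, nrow(beads)), re = NULL) {
  topo <- structure(list(beads = beads, bonds = bonds, angles = angles,
                         dihedrals = dihedrals, contacts = contacts,
                         fixed = fixed, re = re),
                    class = "cg_topology")
  validate_topology(topo)
  topo
}

empty_bonds <- function() {
  data.frame(i = integer(), j = integer(), kf = numeric(), r0 = numeric(),
             cat = character())
}
empty_angles <- function() {
  data.frame(i = integer(), j = integer(), k = integer(), type = character(),
             kf = numeric(), th0 = numeric(), class = integer(),
             cat = character())
}
empty_dihedrals <- function() {
  data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
             type = character(), kf = numeric(), phi0 = numeric(),
             class = integer(), cat = character())
}

#' Contact list constructor
#'
#' Structure-based (Go) pair list. Categories: `intra` (within a folded
#' domain or reference interface), `core_re`, `core_core`, `linker`,
#' `dna_stack`, `dna_pair`.
#'
#' @param i,j bead indices (i < j enforced by sorting).
#' @param r0 native distances in Angstrom (> 0).
#' @param eps well depths in kcal/mol (>= 0).
#' @param cat category string per pair.
#' @return data.frame of class `cg_contacts`.
#' @export
cg_contacts <- function(i, j, r0, eps, cat) {
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  df <- data.frame(i = as.integer(i), j = as.integer(j), r0 = r0, eps = eps,
                   cat = cat)
  stopifnot(all(df$r0 > 0), all(df$eps >= 0), all(df$i < df$j))
  if (anyDuplicated(df[, c("i", "j", "cat")]))
    stop("duplicate contact pairs")
  class(df) <- c("cg_contacts", "data.frame")
  df
}

empty_contacts <- function() {
  cg_contacts(integer(), integer(), numeric(), numeric(), character())
}

#' @export
rbind_contacts <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  cg_contacts(df$i, df$j, df$r0, df$eps, df$cat)
}

validate_topology <- function(topo) {
  n <- nrow(topo$beads)
  stopifnot(length(topo$fixed) == n)
  need <- c("chain", "resid", "kind", "name", "charge", "domain", "subunit")
  stopifnot(all(need %in% names(topo$beads)))
  stopifnot(all(topo$beads$kind %in% c("CA", "P", "S", "B")))
  idx <- c(topo$bonds$i, topo$bonds$j, topo$angles$i, topo$angles$j,
           topo$angles$k, topo$dihedrals$i, topo$dihedrals$j,
           topo$dihedrals$k, topo$dihedrals$l, topo$contacts$i,
           topo$contacts$j)
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    stop("bonded/contact term references a bead outside 1..", n)
  if (anyDuplicated(topo$bonds[, c("i", "j")]))
    stop("duplicate bonds")
  invisible(topo)
}

#' Number of beads
#' @param topo a `cg_topology`.
#' @export
n_beads <- function(topo) nrow(topo$beads)

#' Total charge bookkeeping
#'
#' Exact total charge: (#Lys + #His + #Arg) - (#Asp + #Glu) - (#phosphates),
#' adjusted by any neutralization applied at build time.
#' @param topo a `cg_topology`.
#' @return total charge in units of e.
#' @export
total_charge <- function(topo) sum(topo$beads$charge)

#' Concatenate topologies into one system
#'
#' Offsets all bead indices; chains and subunits are renumbered to stay
#' unique. Coordinates, if supplied, are stacked in the same order.
#'
#' @param topos list of `cg_topology` objects.
#' @param coords optional list of coordinate matrices (n_i x 3).
#' @return a `cg_topology` (with `$coords` if coordinates were given).
#' @export
combine_topologies <- function(topos, coords = NULL) {
  off <- 0L; chain_off <- 0L; sub_off <- 0L
  beads <- list(); bonds <- list(); angles <- list(); dihs <- list()
  cons <- list(); fixed <- list(); re <- NULL
  for (tp in topos) {
    b <- tp$beads
    b$chain <- b$chain + chain_off
    b$subunit <- ifelse(is.na(b$subunit), NA_integer_, b$subunit + sub_off)
    beads[[length(beads) + 1]] <- b
    bd <- tp$bonds; bd$i <- bd$i + off; bd$j <- bd$j + off
    bonds[[length(bonds) + 1]] <- bd
    an <- tp$angles
    an$i <- an$i + off; an$j <- an$j + off; an$k <- an$k + off
    angles[[length(angles) + 1]] <- an
    dh <- tp$dihedrals
    dh$i <- dh$i + off; dh$j <- dh$j + off; dh$k <- dh$k + off
    dh$l <- dh$l + off
    dihs[[length(dihs) + 1]] <- dh
    cn <- as.data.frame(tp$contacts); cn$i <- cn$i + off; cn$j <- cn$j + off
    cons[[length(cons) + 1]] <- cn
    fixed[[length(fixed) + 1]] <- tp$fixed
    if (!is.null(tp$re)) { re <- tp$re; re$bead_offset <- off }
    off <- off + nrow(b)
    chain_off <- max(b$chain)
    sub_off <- max(c(sub_off, b$subunit), na.rm = TRUE)
  }
  cn <- do.call(rbind, cons)
  topo <- cg_topology(do.call(rbind, beads), do.call(rbind, bonds),
                      do.call(rbind, angles), do.call(rbind, dihs),
                      cg_contacts(cn$i, cn$j, cn$r0, cn$eps, cn$cat),
                      unlist(fixed), re = re)
  for (tp in topos) {           # DNA bookkeeping survives combination
    if (!is.null(tp$n_bp)) {
      topo$n_bp <- tp$n_bp
      topo$strand_offset <- tp$strand_offset
    }
  }
  if (!is.null(coords)) topo$coords <- do.call(rbind, coords)
  topo
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology:", nrow(x$beads), "beads,",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals,", nrow(x$contacts), "contacts\n")
  cat("  total charge:", total_charge(x), "e;",
      sum(x$fixed), "fixed beads\n")
  invisible(x)
}
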