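#' Domain map constructor
#'
#' Named, 1-based inclusive residue ranges per subunit. Ranges must be
#' disjoint, contiguous and cover the whole sequence.
#'
#' @param name,start,end,folded,linker vectors describing each domain.
#' @return data.frame of class `cg_domain_map`.
#' @export
domain_map <- function(name, start, end, folded, linker = rep(FALSE, length(name))) {
  dm <- data.frame(name = name, start = as.integer(start),
                   end = as.integer(end), folded = folded, linker = linker)
  dm <- dm[order(dm$start), ]
  if (dm$start[1] != 1L) stop("domain map must start at residue 1")
  if (nrow(dm) > 1 && any(dm$start[-1] != dm$end[-nrow(dm)] + 1L))
    stop("domain ranges must be contiguous and disjoint")
  class(dm) <- c("cg_domain_map", "data.frame")
  dm
}

#' The p53 domain map
#'
#' NTD 1-90 and CTD 357-393 are intrinsically disordered, the Core 91-289
#' and tetramerization (TET) domain 326-356 are folded, and the linker
#' 290-325 tethers Core to TET.
#' @return a `cg_domain_map` covering residues 1-393.
#' @export
p53_domain_map <- function() {
  domain_map(name = c("NTD", "Core", "Linker", "TET", "CTD"),
             start = c(1, 91, 290, 326, 357),
             end = c(90, 289, 325, 356, 393),
             folded = c(FALSE, TRUE, FALSE, TRUE, FALSE),
             linker = c(FALSE, FALSE, TRUE, FALSE, FALSE))
}

.domain_of <- function(dm, resid) {
  out <- character(length(resid))
  for (r in seq_len(nrow(dm)))
    out[resid >= dm$start[r] & resid <= dm$end[r]] <- dm$name[r]
  out
}

#' Build a one-bead-per-residue protein topology
#'
#' Each residue becomes one Calpha bead. Folded domains (per the domain map)
#' get native bonded values and intra-domain Go contacts from the supplied
#' native coordinates; disordered regions get generic local terms driven by
#' the statistical tables and carry no intra-domain structure-based contacts.
#' Charges: +1e Lys/His/Arg, -1e Asp/Glu; `neutralize_ctd` zeroes the Lys
#' charges inside the CTD domain (acetylation mimic).
#'
#' @param sequence one-letter amino-acid string.
#' @param dm a `cg_domain_map`; its ranges must cover the sequence.
#' @param native_coords named list of (n_dom x 3) matrices, one per folded
#'   domain.
#' @param neutralize_ctd logical; zero the CTD lysine charges.
#' @param ff force field supplying spring constants, contact parameters.
#' @param subunit integer tag stored per bead.
#' @return `cg_topology` with `$contacts` (intra-domain) and `$coords`
#'   (native coordinates for folded domains, an extended chain elsewhere).
#' @export
build_protein_topology <- function(sequence, dm = p53_domain_map(),
                                   native_coords = NULL,
                                   neutralize_ctd = FALSE,
                                   ff = default_forcefield(), subunit = 1L) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (n != max(dm$end))
    stop("sequence length (", n, ") does not match domain map (1..",
         max(dm$end), ")")
  bad <- setdiff(aa, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  if (length(bad)) stop("invalid residues: ", paste(bad, collapse = ","))
  folded_doms <- dm$name[dm$folded]
  for (d in folded_doms) {
    if (is.null(native_coords[[d]]))
      stop("missing native coordinates for folded domain ", d)
    nd <- dm$end[dm$name == d] - dm$start[dm$name == d] + 1L
    if (nrow(native_coords[[d]]) != nd)
      stop("native coordinates for ", d, " must have ", nd, " rows")
  }
  resid <- seq_len(n)
  dom <- .domain_of(dm, resid)
  charge <- .aa_charge(aa)
  if (neutralize_ctd) {
    if (!"CTD" %in% dm$name) stop("neutralize_ctd requires a CTD domain")
    charge[dom == "CTD" & aa == "K"] <- 0
  }
  beads <- data.frame(chain = 1L, resid = resid, kind = "CA", name = aa,
                      charge = charge, domain = dom, subunit = subunit)

  # assemble coordinates: folded domains native, others extended (3.8 A rise)
  coords <- matrix(NA_real_, n, 3)
  for (d in folded_doms) {
    rng <- dm$start[dm$name == d]:dm$end[dm$name == d]
    coords[rng, ] <- native_coords[[d]]
  }
  step <- c(3.8, 0, 0)
  if (any(is.na(coords[1, ]))) coords[1, ] <- c(0, 0, 0)
  for (i in seq_len(n)[-1])
    if (any(is.na(coords[i, ]))) coords[i, ] <- coords[i - 1, ] + step

  same_folded <- function(idx) {
    d <- dom[idx]
    all(d == d[1]) && d[1] %in% folded_doms
  }
  dvec <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))

  bi <- seq_len(n - 1)
  bonds <- data.frame(i = bi, j = bi + 1L, kf = ff$k_bond,
                      r0 = ff$bond_r0_disordered, cat = "disordered")
  for (t in seq_len(nrow(bonds))) {
    if (same_folded(c(bonds$i[t], bonds$j[t]))) {
      bonds$r0[t] <- dvec(bonds$i[t], bonds$j[t])
      bonds$cat[t] <- "folded"
    }
  }
  angles <- empty_angles()
  if (n >= 3) {
    ai <- seq_len(n - 2)
    angles <- data.frame(i = ai, j = ai + 1L, k = ai + 2L, type = "table",
                         kf = 1.0, th0 = NA_real_, class = 1L,
                         cat = "disordered")
    for (t in seq_len(nrow(angles))) {
      idx <- c(angles$i[t], angles$j[t], angles$k[t])
      if (same_folded(idx)) {
        angles$type[t] <- "harm"; angles$kf[t] <- ff$k_angle
        angles$th0[t] <- .angle_of(coords, idx); angles$cat[t] <- "folded"
      }
    }
  }
  dihedrals <- empty_dihedrals()
  if (n >= 4) {
    di <- seq_len(n - 3)
    dihedrals <- data.frame(i = di, j = di + 1L, k = di + 2L, l = di + 3L,
                            type = "table", kf = 1.0, phi0 = NA_real_,
                            class = 1L, cat = "disordered")
    for (t in seq_len(nrow(dihedrals))) {
      idx <- c(dihedrals$i[t], dihedrals$j[t], dihedrals$k[t], dihedrals$l[t])
      if (same_folded(idx)) {
        dihedrals$type[t] <- "cos"; dihedrals$kf[t] <- ff$k_dihedral
        dihedrals$phi0[t] <- .dihedral_of(coords, idx)
        dihedrals$cat[t] <- "folded"
      }
    }
  }
  cons <- list()
  for (d in folded_doms) {
    rng <- dm$start[dm$name == d]:dm$end[dm$name == d]
    cm <- native_contact_map(coords[rng, , drop = FALSE],
                             cutoff = ff$contact_cutoff,
                             min_seq_sep = ff$contact_min_seq_sep,
                             eps = ff$eps_intra)
    cm$i <- cm$i + rng[1] - 1L; cm$j <- cm$j + rng[1] - 1L
    cons[[d]] <- as.data.frame(cm)
  }
  cons <- if (length(cons)) do.call(rbind, cons) else as.data.frame(empty_contacts())
  topo <- cg_topology(beads, bonds, angles, dihedrals,
                      cg_contacts(cons$i, cons$j, cons$r0, cons$eps, cons$cat))
  topo$coords <- coords
  topo
}

.angle_of <- function(coords, idx) {
  a <- coords[idx[1], ] - coords[idx[2], ]
  b <- coords[idx[3], ] - coords[idx[2], ]
  acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
}

.dihedral_of <- function(coords, idx) {
  b1 <- coords[idx[2], ] - coords[idx[1], ]
  b2 <- coords[idx[3], ] - coords[idx[2], ]
  b3 <- coords[idx[4], ] - coords[idx[3], ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
         n1[1] * b2[2] - n1[2] * b2[1])
  atan2(sum(m * n2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Native contact map from coordinates
#'
#' All bead pairs at least `min_seq_sep` apart in sequence and within
#' `cutoff` in space, with the native distance as `r0`.
#'
#' @param coords n x 3 coordinate matrix.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @param min_seq_sep minimum |i - j|.
#' @param eps well depth assigned to every pair.
#' @param cat contact category.
#' @return `cg_contacts`.
#' @export
native_contact_map <- function(coords, cutoff = 6.5, min_seq_sep = 4,
                               eps = 0.3, cat = "intra") {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (any(!is.finite(coords))) stop("incomplete coordinates")
  n <- nrow(coords)
  if (n < 2) return(empty_contacts())
  dm <- as.matrix(dist(coords))
  sel <- which(upper.tri(dm) & dm <= cutoff &
                 abs(row(dm) - col(dm)) >= min_seq_sep, arr.ind = TRUE)
  if (!nrow(sel)) return(empty_contacts())
  cg_contacts(sel[, 1], sel[, 2], dm[sel], rep(eps, nrow(sel)),
              rep(cat, nrow(sel)))
}

# --- DNA ---------------------------------------------------------------------

.complement <- c(A = "T", C = "G", G = "C", T = "A")

# bead layout per strand, 5'->3': nt i contributes (P_i if i > 1), S_i, B_i.
# Returns data.frame(row index -> strand nt/bp/kind) for one strand of n nt.
.dna_strand_layout <- function(n) {
  kind <- character(0); nt <- integer(0)
  for (i in seq_len(n)) {
    if (i > 1) { kind <- c(kind, "P"); nt <- c(nt, i) }
    kind <- c(kind, "S", "B"); nt <- c(nt, i, i)
  }
  data.frame(nt = nt, kind = kind)
}

# helix placement parameters (simplified B-form): rise/twist per bp, per-kind
# radius and phase; strand 2 offset 154 deg, antiparallel.
.bdna_geom <- list(rise = 3.38, twist = 36 * pi / 180,
                   r = c(P = 8.9, S = 6.9, B = 2.0),
                   phase = c(P = -18 * pi / 180, S = 0, B = 40 * pi / 180),
                   strand2_offset = 154 * pi / 180)

#' Ideal straight B-DNA coordinates
#'
#' Deterministic reference geometry: helix axis along z, rise 3.38 A/bp,
#' twist 36 deg/bp, beads placed at fixed per-kind radii. Bead order matches
#' [build_dna_topology()] (strand 1 then strand 2; per nucleotide P, S, B
#' with the 5'-terminal phosphate omitted).
#'
#' @param n_bp number of base pairs (>= 2).
#' @param duplex logical; if FALSE only strand 1 beads are returned.
#' @return coordinate matrix (n_beads x 3), in Angstrom.
#' @export
ideal_bdna_coords <- function(n_bp, duplex = TRUE) {
  if (n_bp < 2) stop("n_bp must be >= 2")
  g <- .bdna_geom
  place <- function(bp_frac, kind, strand) {
    th <- (bp_frac - 1) * g$twist + g$phase[[kind]] +
      if (strand == 2) g$strand2_offset else 0
    # strand 2 bases point back toward strand 1
    if (strand == 2 && kind == "B") th <- th - 2 * g$phase[["B"]] + 0
    c(g$r[[kind]] * cos(th), g$r[[kind]] * sin(th), (bp_frac - 1) * g$rise)
  }
  rows <- list()
  lay <- .dna_strand_layout(n_bp)
  for (t in seq_len(nrow(lay))) {
    i <- lay$nt[t]; kind <- lay$kind[t]
    bp <- if (kind == "P") i - 0.5 else i
    rows[[length(rows) + 1]] <- place(bp, kind, 1)
  }
  if (duplex) {
    for (t in seq_len(nrow(lay))) {
      j <- lay$nt[t]; kind <- lay$kind[t]
      bp <- n_bp + 1 - j         # strand 2 nt j pairs with bp n+1-j
      if (kind == "P") bp <- bp + 0.5
      rows[[length(rows) + 1]] <- place(bp, kind, 2)
    }
  }
  do.call(rbind, rows)
}

#' Build a three-beads-per-nucleotide DNA topology
#'
#' Per strand of n nucleotides: n sugar (S) and n base (B) beads and n-1
#' phosphate (P) beads -- the 5'-terminal phosphate is omitted. Phosphates
#' carry -1e. Bonded terms (S-P/P-S/S-B bonds, backbone angles, backbone
#' dihedrals) take their native values from the ideal straight B-form
#' geometry, so the straight helix is the bonded-energy minimum. For a
#' duplex the complementary strand is generated automatically and
#' intra-strand base stacking plus Watson-Crick base-pair Go contacts
#' (eps_AT < eps_GC) are added.
#'
#' @param sequence strand-1 sequence over A/C/G/T, 5' to 3'.
#' @param duplex build the complementary strand too (default TRUE).
#' @param ff force field (DNA spring constants and contact strengths).
#' @param re optional RE annotation from [annotate_re()].
#' @return `cg_topology` with `$coords` set to the ideal B-form geometry.
#' @export
build_dna_topology <- function(sequence, duplex = TRUE,
                               ff = default_forcefield(), re = NULL) {
  s1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(s1)) stop("empty sequence")
  if (!all(s1 %in% names(.complement)))
    stop("invalid characters in DNA sequence")
  n <- length(s1)
  if (!duplex && n == 1) {
    beads <- data.frame(chain = 1L, resid = 1L, kind = c("S", "B"),
                        name = c(s1, s1), charge = 0, domain = "DNA",
                        subunit = NA_integer_)
    topo <- cg_topology(beads)
    topo$coords <- matrix(c(6.9, 0, 0, 2.0 * cos(0.7), 2.0 * sin(0.7), 0),
                          2, 3, byrow = TRUE)
    return(topo)
  }
  if (n < 2) stop("duplex requires >= 2 bp")
  s2 <- rev(unname(.complement[s1]))  # 5'->3' of complementary strand
  lay <- .dna_strand_layout(n)
  mk_beads <- function(lay, seqv, chain) {
    data.frame(chain = chain, resid = lay$nt, kind = lay$kind,
               name = seqv[lay$nt],
               charge = ifelse(lay$kind == "P", -1, 0),
               domain = "DNA", subunit = NA_integer_)
  }
  beads <- mk_beads(lay, s1, 1L)
  nb1 <- nrow(beads)
  if (duplex) beads <- rbind(beads, mk_beads(lay, s2, 2L))
  coords <- ideal_bdna_coords(n, duplex = duplex)

  # index helpers: bead row of kind at nt i on strand s
  idx_of <- function(strand, i, kind) {
    base <- if (strand == 1) 0L else nb1
    off <- which(lay$nt == i & lay$kind == kind)
    if (!length(off)) return(NA_integer_)
    base + off
  }
  dvec <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  bonds <- list(); angles <- list(); dihs <- list()
  add_bond <- function(i, j) {
    bonds[[length(bonds) + 1]] <<- data.frame(
      i = i, j = j, kf = ff$dna$k_bond, r0 = dvec(i, j), cat = "dna")
  }
  add_angle <- function(i, j, k) {
    angles[[length(angles) + 1]] <<- data.frame(
      i = i, j = j, k = k, type = "harm", kf = ff$dna$k_angle,
      th0 = .angle_of(coords, c(i, j, k)), class = 1L, cat = "dna")
  }
  add_dih <- function(i, j, k, l) {
    dihs[[length(dihs) + 1]] <<- data.frame(
      i = i, j = j, k = k, l = l, type = "cos", kf = ff$dna$k_dihedral,
      phi0 = .dihedral_of(coords, c(i, j, k, l)), class = 1L, cat = "dna")
  }
  strands <- if (duplex) 1:2 else 1
  for (s in strands) {
    for (i in seq_len(n)) {
      add_bond(idx_of(s, i, "S"), idx_of(s, i, "B"))
      if (i > 1) {
        add_bond(idx_of(s, i - 1, "S"), idx_of(s, i, "P"))
        add_bond(idx_of(s, i, "P"), idx_of(s, i, "S"))
      }
    }
    for (i in 2:n) {
      add_angle(idx_of(s, i - 1, "S"), idx_of(s, i, "P"), idx_of(s, i, "S"))
      add_angle(idx_of(s, i, "P"), idx_of(s, i, "S"), idx_of(s, i, "B"))
      if (i < n)
        add_angle(idx_of(s, i, "P"), idx_of(s, i, "S"), idx_of(s, i + 1, "P"))
    }
    if (n >= 3) {
      for (i in 2:(n - 1)) {
        add_dih(idx_of(s, i - 1, "S"), idx_of(s, i, "P"), idx_of(s, i, "S"),
                idx_of(s, i + 1, "P"))
        add_dih(idx_of(s, i, "P"), idx_of(s, i, "S"), idx_of(s, i + 1, "P"),
                idx_of(s, i + 1, "S"))
      }
    }
  }
  cons <- list()
  for (s in strands) {  # intra-strand base stacking
    for (i in seq_len(n - 1)) {
      bi <- idx_of(s, i, "B"); bj <- idx_of(s, i + 1, "B")
      cons[[length(cons) + 1]] <- data.frame(
        i = bi, j = bj, r0 = dvec(bi, bj), eps = ff$dna$eps_stack,
        cat = "dna_stack")
    }
  }
  if (duplex) {
    for (i in seq_len(n)) {   # Watson-Crick pairs: strand1 nt i <-> strand2 nt n+1-i
      bi <- idx_of(1, i, "B"); bj <- idx_of(2, n + 1 - i, "B")
      eps <- if (s1[i] %in% c("A", "T")) ff$dna$eps_bp_AT else ff$dna$eps_bp_GC
      cons[[length(cons) + 1]] <- data.frame(
        i = bi, j = bj, r0 = dvec(bi, bj), eps = eps, cat = "dna_pair")
    }
  }
  cons <- if (length(cons)) do.call(rbind, cons) else as.data.frame(empty_contacts())
  topo <- cg_topology(beads, do.call(rbind, bonds), do.call(rbind, angles),
                      if (length(dihs)) do.call(rbind, dihs) else empty_dihedrals(),
                      cg_contacts(cons$i, cons$j, cons$r0, cons$eps, cons$cat),
                      re = re)
  topo$coords <- coords
  topo$n_bp <- n
  topo$strand_offset <- nb1
  topo
}

#' Sugar-bead indices along one strand, ordered by base-pair index
#' @param topo a DNA `cg_topology` from [build_dna_topology()].
#' @param strand 1 or 2.
#' @return integer bead indices, element i = sugar at bp i.
#' @export
dna_sugar_indices <- function(topo, strand = 1) {
  b <- topo$beads
  sel <- which(b$kind == "S" & b$chain == strand)
  nt <- b$resid[sel]
  if (strand == 2) nt <- topo$n_bp + 1 - nt   # convert nt index to bp index
  sel[order(nt)]
}

#' Annotate a response element on a duplex
#'
#' Two 10-bp half-sites separated by a spacer. Quarter-sites (5 bp each) are
#' numbered 1..4 along the duplex and are the Core footprints.
#'
#' @param n_bp duplex length.
#' @param re_start first bp of half-site 1 (production preset: 11, i.e. the
#'   RE starts 10 bp from one duplex end).
#' @param spacer spacer length in bp (>= 0).
#' @param sequence optional strand-1 sequence; if given, both half-sites are
#'   validated against the RRRCWWGYYY consensus.
#' @return list of class `cg_re_annotation`.
#' @export
annotate_re <- function(n_bp, re_start = 11, spacer = 0, sequence = NULL) {
  stopifnot(spacer >= 0, re_start >= 1)
  h1 <- c(re_start, re_start + 9)
  h2 <- c(re_start + 10 + spacer, re_start + 19 + spacer)
  if (h2[2] > n_bp) stop("RE does not fit on ", n_bp, " bp duplex")
  if (!is.null(sequence)) {
    s <- strsplit(toupper(sequence), "")[[1]]
    for (h in list(h1, h2)) .check_halfsite(s[h[1]:h[2]])
  }
  quarters <- list(c(h1[1], h1[1] + 4), c(h1[1] + 5, h1[2]),
                   c(h2[1], h2[1] + 4), c(h2[1] + 5, h2[2]))
  structure(list(n_bp = n_bp, half_site1 = h1, half_site2 = h2,
                 spacer = spacer, quarters = quarters),
            class = "cg_re_annotation")
}

.halfsite_classes <- list(R = c("A", "G"), W = c("A", "T"), Y = c("C", "T"),
                          C = "C", G = "G")

.check_halfsite <- function(bases) {
  pat <- c("R", "R", "R", "C", "W", "W", "G", "Y", "Y", "Y")
  ok <- mapply(function(b, p) b %in% .halfsite_classes[[p]], bases, pat)
  if (!all(ok))
    stop("half-site does not match RRRCWWGYYY at positions ",
         paste(which(!ok), collapse = ","))
  invisible(TRUE)
}

#' A consensus RE sequence generator (AAACATGTTT half-sites)
#' @param n_bp duplex length; @param re_start,spacer RE placement.
#' @return strand-1 sequence string with the RE embedded in poly-A/T flanks.
#' @export
re_sequence <- function(n_bp, re_start = 11, spacer = 0) {
  half <- "AAACATGTTT"
  s <- rep("A", n_bp)
  h <- strsplit(half, "")[[1]]
  s[re_start:(re_start + 9)] <- h
  s2 <- re_start + 10 + spacer
  s[s2:(s2 + 9)] <- h
  paste(s, collapse = "")
}
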