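# atom-name field per bead kind (CG dialect): CA, DP, DS, DB
.kind_to_atom <- c(CA = "CA", P = "DP", S = "DS", B = "DB")
.atom_to_kind <- c(CA = "CA", DP = "P", DS = "S", DB = "B")

#' Write a coarse-grained PDB
#'
#' One ATOM record per bead; the bead kind goes in the atom-name field
#' (CA/DP/DS/DB), the charge (units of e) in the occupancy column so the
#' topology round-trips, the domain label in the segment field.
#'
#' @param topo `cg_topology`; @param coords n x 3 matrix; @param path file.
#' @export
write_cg_pdb <- function(topo, coords, path) {
  b <- topo$beads
  n <- nrow(b)
  stopifnot(nrow(coords) == n)
  chains <- c(LETTERS, letters, 0:9)
  lines <- character(n)
  for (i in seq_len(n)) {
    resname <- substr(sprintf("%-3s", b$name[i]), 1, 3)
    lines[i] <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
      i %% 100000, .kind_to_atom[[b$kind[i]]], resname,
      chains[((b$chain[i] - 1) %% length(chains)) + 1], b$resid[i] %% 10000,
      coords[i, 1], coords[i, 2], coords[i, 3], b$charge[i], 0,
      substr(b$domain[i], 1, 4))
  }
  writeLines(c("REMARK   p53cg coarse-grained model", lines, "END"), path)
  invisible(path)
}

#' Read a coarse-grained PDB
#'
#' Strict mode rejects unknown atom names and malformed ATOM records,
#' reporting the offending line number; lenient mode skips them.
#'
#' @param path file path; @param strict logical (default TRUE).
#' @return list(topology = `cg_topology` (beads only; bonded terms are not
#'   stored in PDB), coords).
#' @export
read_cg_pdb <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rows <- list(); xyz <- list()
  chains <- c(LETTERS, letters, 0:9)
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    rec <- substr(l, 1, 6)
    if (!startsWith(rec, "ATOM")) {
      if (strict && !grepl("^(REMARK|END|TER|HETATM|MODEL|ENDMDL|CRYST|$)",
                           l))
        stop("unknown record at line ", ln, ": ", substr(l, 1, 20))
      next
    }
    atom <- trimws(substr(l, 13, 16))
    if (!atom %in% names(.atom_to_kind)) {
      if (strict) stop("unknown bead kind '", atom, "' at line ", ln)
      next
    }
    x <- suppressWarnings(as.numeric(substr(l, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(l, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(l, 47, 54)))
    occ <- suppressWarnings(as.numeric(substr(l, 55, 60)))
    resid <- suppressWarnings(as.integer(substr(l, 23, 26)))
    if (anyNA(c(x, y, z, resid)))
      stop("malformed ATOM record at line ", ln)
    ch <- substr(l, 22, 22)
    rows[[length(rows) + 1]] <- data.frame(
      chain = match(ch, chains), resid = resid,
      kind = .atom_to_kind[[atom]], name = trimws(substr(l, 18, 20)),
      charge = ifelse(is.na(occ), 0, occ), domain = trimws(substr(l, 67, 70)),
      subunit = NA_integer_)
    xyz[[length(xyz) + 1]] <- c(x, y, z)
  }
  if (!length(rows)) stop("no ATOM records in ", path)
  beads <- do.call(rbind, rows)
  topo <- cg_topology(beads)
  list(topology = topo, coords = do.call(rbind, xyz))
}
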