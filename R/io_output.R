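#' Write a trajectory as XYZ
#'
#' Plain multi-frame XYZ; element column carries the bead kind. Fixed
#' decimal format (3 places) so golden-file comparisons are byte-stable.
#'
#' @param traj `cg_trajectory`; @param topo topology (bead kinds);
#' @param path output file.
#' @export
write_xyz <- function(traj, topo, path) {
  frames <- traj$frames
  n <- dim(frames)[1]; nf <- dim(frames)[3]
  kinds <- topo$beads$kind
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(c(as.character(n), paste("frame", f, "step",
                                        traj$steps[f])), con)
    writeLines(sprintf("%-2s %12.3f %12.3f %12.3f", kinds,
                       frames[, 1, f], frames[, 2, f], frames[, 3, f]), con)
  }
  invisible(path)
}

#' Write a tab-separated table with a commented header
#' @param df data.frame; @param path file; @param comment header lines.
#' @export
write_tsv <- function(df, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste("#", cm), con)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an occupancy grid in DX format
#'
#' OpenDX-style text volumetric grid (origin, deltas, counts, values) for
#' iso-surface viewing.
#'
#' @param grid `cg_occupancy_grid`; @param path file; @param what
#'   `"prob"` or `"counts"`.
#' @export
write_dx <- function(grid, path, what = c("prob", "counts")) {
  what <- match.arg(what)
  v <- grid[[what]]
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.3f %.3f %.3f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.3f 0 0", grid$voxel),
    sprintf("delta 0 %.3f 0", grid$voxel),
    sprintf("delta 0 0 %.3f", grid$voxel),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2],
            d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.numeric(aperm(v, c(3, 2, 1)))  # DX wants z fastest
  full <- length(vals) - length(vals) %% 3
  if (full > 0) {
    m <- matrix(vals[seq_len(full)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(vals) > full)
    writeLines(paste(sprintf("%.6e", vals[(full + 1):length(vals)]),
                     collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
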