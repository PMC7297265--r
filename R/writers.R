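## Output writers: NMD (Normal Mode Wizard), multi-model PDB trajectories,
## CSV eigen tables, and a plain PDB point writer.

#' Write normal modes to NMD, PDB trajectory, or CSV
#'
#' `"nmd"` writes the Normal Mode Wizard dialect (coordinates plus one
#' `mode` line per mode carrying the eigenvector, readable by VMD/ProDy
#' viewers and by [read_nmd()]).  `"pdb"` writes a multi-model trajectory
#' sampling one full oscillation period of a single mode at a stated
#' amplitude (first and last frames coincide).  `"csv"` writes the
#' eigenvalue/wavenumber table.
#'
#' @param points The [point_set] the modes belong to.
#' @param modeset A `mode_set`.
#' @param path Output file.
#' @param format `"nmd"`, `"pdb"` or `"csv"`.
#' @param modes Mode indices to write (default: all non-rigid); for
#'   `"pdb"`, a single index.
#' @param amplitude Oscillation amplitude in A for trajectories (default 2).
#' @param n_frames Frames over one period, endpoint included (default 21).
#' @return Invisibly, `path`.
#' @export
write_modes <- function(points, modeset, path,
                        format = c("nmd", "pdb", "csv"),
                        modes = NULL, amplitude = 2, n_frames = 21) {
  stopifnot(inherits(points, "point_set"), inherits(modeset, "mode_set"))
  format <- match.arg(format)
  nm <- length(modeset$values)
  if (is.null(modes))
    modes <- if (format == "pdb") modeset$n_rigid + 1L
             else seq(modeset$n_rigid + 1L, nm)
  if (any(modes < 1L | modes > nm))
    stop("mode index out of range 1..", nm)
  switch(format,
    nmd = .write_nmd(points, modeset, path, modes),
    pdb = .write_traj(points, modeset, path, modes[1], amplitude, n_frames),
    csv = utils::write.csv(
      data.frame(mode = seq_len(nm),
                 eigenvalue = modeset$values,
                 wavenumber_cm1 = modeset$wavenumbers,
                 rigid = seq_len(nm) <= modeset$n_rigid),
      path, row.names = FALSE))
  invisible(path)
}

.write_nmd <- function(points, modeset, path, modes) {
  n <- nrow(points$coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("nmwiz_load generated by aesm", con)
  writeLines(paste("names", paste(rep("CA", n), collapse = " ")), con)
  writeLines(paste("resids", paste(seq_len(n), collapse = " ")), con)
  writeLines(paste("coordinates",
                   paste(sprintf("%.3f", as.vector(t(points$coords))),
                         collapse = " ")), con)
  for (m in modes) {
    v <- modeset$vectors[, m]
    writeLines(paste("mode", m, sprintf("%.6g", modeset$wavenumbers[m]),
                     paste(sprintf("%.6e", v), collapse = " ")), con)
  }
}

#' Read an NMD file written by [write_modes()]
#'
#' @param path NMD file.
#' @return List with `coordinates` (N x 3), `modes` (3N x k matrix),
#'   `mode_ids`, `wavenumbers`.
#' @export
read_nmd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getv <- function(tag) {
    l <- grep(paste0("^", tag, " "), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(substring(l, nchar(tag) + 2)), " +")[[1]])
  }
  xyz <- getv("coordinates")
  ml <- grep("^mode ", lines, value = TRUE)
  parsed <- lapply(ml, function(l) {
    v <- as.numeric(strsplit(trimws(substring(l, 6)), " +")[[1]])
    list(id = v[1], w = v[2], vec = v[-(1:2)])
  })
  list(coordinates = matrix(xyz, ncol = 3, byrow = TRUE),
       modes = do.call(cbind, lapply(parsed, `[[`, "vec")),
       mode_ids = vapply(parsed, `[[`, numeric(1), "id"),
       wavenumbers = vapply(parsed, `[[`, numeric(1), "w"))
}

.write_traj <- function(points, modeset, path, mode, amplitude, n_frames) {
  v <- matrix(modeset$vectors[, mode], ncol = 3, byrow = TRUE)
  vn <- v / sqrt(max(rowSums(v^2)))     # peak node excursion = amplitude
  phases <- seq(0, 2 * pi, length.out = n_frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(phases)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- points$coords + amplitude * sin(phases[f]) * vn
    .write_atom_lines(con, xyz, points$labels,
                      if (is.null(points$bfactors)) rep(0, nrow(xyz))
                      else points$bfactors)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

.write_atom_lines <- function(con, xyz, labels, b) {
  n <- nrow(xyz)
  writeLines(sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n) %% 100000, seq_len(n) %% 10000,
    xyz[, 1], xyz[, 2], xyz[, 3], rep(1, n), pmin(b, 999.99)), con)
}

#' Write a point set as a PDB-like file
#'
#' One CA pseudo-atom per point; masses are not representable in PDB and
#' are written to the B-factor column only when `bfactors` are absent.
#'
#' @param points A [point_set].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_points_pdb <- function(points, path) {
  stopifnot(inherits(points, "point_set"))
  con <- file(path, "w")
  on.exit(close(con))
  b <- if (is.null(points$bfactors)) rep(0, nrow(points$coords))
       else points$bfactors
  .write_atom_lines(con, points$coords, points$labels, b)
  writeLines("END", con)
  invisible(path)
}
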