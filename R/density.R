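## Cryo-EM density maps: MRC/CCP4-2014 reading and writing, voxel export.

#' Density grid
#'
#' A 3-D scalar field on a regular grid: `origin` (A, position of the first
#' voxel center), `spacing` (A per voxel along x, y, z) and `values`
#' (array indexed \[x, y, z\]).
#'
#' @param origin Length-3 numeric (A).
#' @param spacing Length-3 positive numeric (A).
#' @param values 3-D numeric array with all dimensions >= 2.
#' @return A `density_grid` object.
#' @export
density_grid <- function(origin, spacing, values) {
  spacing <- rep_len(as.numeric(spacing), 3)
  stopifnot(all(spacing > 0), length(dim(values)) == 3,
            all(dim(values) >= 2))
  structure(list(origin = as.numeric(origin)[1:3], spacing = spacing,
                 values = values),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "density_grid: %s voxels, spacing %s A, range [%.3g, %.3g]\n",
    paste(dim(x$values), collapse = "x"),
    paste(format(x$spacing, digits = 3), collapse = ", "),
    min(x$values), max(x$values)))
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Minimal reader for MRC2014 maps (modes 0, 1, 2; little- or big-endian by
#' machine-stamp detection).  The axis order declared in the header
#' (`mapc/mapr/maps`) is normalized so the returned array is always indexed
#' \[x, y, z\]; the origin honours the `ORIGIN` record when set and the
#' start indices otherwise.
#'
#' @param path Path to an `.mrc`/`.map` file.
#' @return A [density_grid].
#' @export
read_density <- function(path) {
  if (!file.exists(path)) stop("cannot read density file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("bad MRC header: file too short")
  endian <- "little"
  int_at <- function(i) readBin(hdr_raw[(4 * i - 3):(4 * i)], "integer",
                                size = 4, endian = endian)
  ## machine stamp (word 54): 0x44 0x44/0x41 little, 0x11 big
  stamp <- as.integer(hdr_raw[213])
  if (stamp == 0x11) endian <- "big"
  nc <- int_at(1); nr <- int_at(2); ns <- int_at(3)
  mode <- int_at(4)
  if (!(mode %in% c(0L, 1L, 2L))) stop("bad MRC header: unsupported mode ",
                                       mode)
  if (any(c(nc, nr, ns) < 1) || any(c(nc, nr, ns) > 1e4))
    stop("bad MRC header: implausible dimensions")
  start <- c(int_at(5), int_at(6), int_at(7))
  mxyz <- c(int_at(8), int_at(9), int_at(10))
  flt_at <- function(i) readBin(hdr_raw[(4 * i - 3):(4 * i)], "double",
                                size = 4, endian = endian)
  cella <- c(flt_at(11), flt_at(12), flt_at(13))
  mapcrs <- c(int_at(17), int_at(18), int_at(19))
  if (!setequal(mapcrs, 1:3)) mapcrs <- 1:3
  origin_rec <- c(flt_at(50), flt_at(51), flt_at(52))
  n_vox <- nc * nr * ns
  what <- if (mode == 2L) "double" else "integer"
  size <- c(`0` = 1L, `1` = 2L, `2` = 4L)[as.character(mode)]
  vals <- readBin(con, what, n = n_vox, size = size, endian = endian,
                  signed = TRUE)
  if (length(vals) < n_vox) stop("bad MRC file: truncated data block")
  a <- array(as.numeric(vals), dim = c(nc, nr, ns))
  ## columns/rows/sections -> x,y,z
  perm <- match(1:3, mapcrs)      # position of x,y,z among (c,r,s)
  a <- aperm(a, perm)
  spacing <- ifelse(mxyz > 0, cella / mxyz, 1)
  start_xyz <- start[perm]
  origin <- if (any(origin_rec != 0)) origin_rec else start_xyz * spacing
  density_grid(origin = origin, spacing = spacing, values = a)
}

#' Write a density grid as an MRC map
#'
#' Mode-2 (float32) MRC2014 writer, x,y,z axis order.
#'
#' @param grid A [density_grid].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_density <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2 = float32
  wi(c(0, 0, 0))              # nstart
  wi(d)                       # mx my mz
  wf(d * grid$spacing)        # cella
  wf(c(90, 90, 90))           # cellb
  wi(1:3)                     # mapc mapr maps
  wf(c(min(grid$values), max(grid$values), mean(grid$values)))
  wi(rep(0, 2))               # ispg, nsymbt
  wi(rep(0, 25))              # extra
  wf(grid$origin)             # origin x y z (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp
  wf(stats::sd(as.numeric(grid$values)))
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  wf(as.numeric(grid$values))
  invisible(path)
}

#' Extract a point set from a density map
#'
#' One point per voxel with density above the threshold, at the voxel
#' center's world coordinates.  Node masses are proportional to the voxel
#' density, uniformly rescaled so the total equals `total_mass` when given
#' (otherwise so the mean node mass is 110 amu, a typical residue mass);
#' this keeps absolute frequencies on a protein-like scale.
#'
#' @param grid A [density_grid].
#' @param threshold Density threshold (strictly above).
#' @param total_mass Optional total molecular mass (amu).
#' @return A [point_set]; labels are the linear voxel indices.
#' @export
points_from_density <- function(grid, threshold, total_mass = NULL) {
  stopifnot(inherits(grid, "density_grid"), is.finite(threshold))
  sel <- which(grid$values > threshold, arr.ind = TRUE)
  if (!nrow(sel)) stop("no voxel above threshold ", format(threshold))
  coords <- sweep(sweep(sel - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  dens <- grid$values[sel]
  ## masses proportional to density; voxels passing a negative threshold
  ## with non-positive density get a small positive floor
  dens <- pmax(dens, 1e-6 * max(dens))
  masses <- dens / sum(dens) *
    (if (is.null(total_mass)) 110 * nrow(sel) else total_mass)
  point_set(coords, masses = masses,
            labels = sprintf("vox%d", which(grid$values > threshold)))
}
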