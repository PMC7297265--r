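#' Synthetic structure fixtures
#'
#' Deterministic point sets and density maps with known geometry, used by the
#' test-suite and examples so that every stage of the modelling pipeline can
#' be exercised without downloading any structure.  `make_lattice` builds an
#' `n^3` cubic lattice whose alpha shape (at large alpha) tessellates a cube
#' of volume `(n-1)^3 spacing^3` exactly; `make_bar` builds a rectangular
#' `nx x ny x nz` lattice bar used for continuum-limit frequency checks;
#' `make_shell` builds a spherical shell of lattice points (a crude capsid);
#' `make_helix` traces an idealized alpha-helical C-alpha path.
#'
#' @param n Points per edge (lattice).
#' @param spacing Lattice constant in Angstrom.
#' @param mass Per-point mass in amu (default 110, a typical residue mass).
#' @return A [point_set].
#' @export
#' @examples
#' ps <- make_lattice(3)
#' nrow(ps$coords)  # 27
make_lattice <- function(n, spacing = 1, mass = 110) {
  stopifnot(n >= 2, spacing > 0)
  g <- seq(0, by = spacing, length.out = n)
  xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
  point_set(xyz, masses = mass,
            labels = sprintf("lat%04d", seq_len(nrow(xyz))))
}

#' @rdname make_lattice
#' @param nx,ny,nz Points per edge along each axis of the bar.
#' @export
make_bar <- function(nx, ny = 3, nz = 3, spacing = 1, mass = 110) {
  stopifnot(nx >= 2, ny >= 2, nz >= 2, spacing > 0)
  xyz <- as.matrix(expand.grid(x = seq(0, by = spacing, length.out = nx),
                               y = seq(0, by = spacing, length.out = ny),
                               z = seq(0, by = spacing, length.out = nz)))
  point_set(xyz, masses = mass,
            labels = sprintf("bar%05d", seq_len(nrow(xyz))))
}

#' @rdname make_lattice
#' @param r_outer,r_inner Outer/inner radius of the shell (A).
#' @export
make_shell <- function(r_outer, r_inner, spacing = 1, mass = 110) {
  stopifnot(r_outer > r_inner, r_inner >= 0, spacing > 0)
  g <- seq(-r_outer, r_outer, by = spacing)
  xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
  r <- sqrt(rowSums(xyz^2))
  xyz <- xyz[r <= r_outer & r >= r_inner, , drop = FALSE]
  point_set(xyz, masses = mass,
            labels = sprintf("shl%05d", seq_len(nrow(xyz))))
}

#' @rdname make_lattice
#' @param n_res Number of residues along the helix.
#' @param rise Rise per residue (A), default 1.5.
#' @param radius Helix radius (A), default 2.3.
#' @param twist Twist per residue in degrees, default 100.
#' @export
make_helix <- function(n_res, rise = 1.5, radius = 2.3, twist = 100,
                       mass = 110) {
  stopifnot(n_res >= 4)
  th <- (seq_len(n_res) - 1) * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th),
               (seq_len(n_res) - 1) * rise)
  point_set(xyz, masses = mass, labels = sprintf("hx%03d", seq_len(n_res)))
}

#' Synthetic spherical density map
#'
#' A cubic density grid with value 1 inside a sphere of the given radius and
#' 0 outside, optionally smoothed with a separable Gaussian kernel.  Used to
#' exercise the density-map path of the pipeline end to end.
#'
#' @param radius Sphere radius (A); must exceed twice the voxel size.
#' @param voxel Voxel edge (A).
#' @param blur_sigma Gaussian blur standard deviation in voxels (0 = binary
#'   map).
#' @param pad Voxels of empty padding around the sphere, default 2.
#' @return A [density_grid].
#' @export
make_sphere_map <- function(radius, voxel = 1, blur_sigma = 0, pad = 2) {
  stopifnot(radius > 2 * voxel, voxel > 0)
  half <- ceiling(radius / voxel) + pad
  g <- (-half:half) * voxel
  n <- length(g)
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  vals <- array(as.numeric(d2 <= radius^2), dim = c(n, n, n))
  if (blur_sigma > 0) {
    k <- stats::dnorm(-ceiling(3 * blur_sigma):ceiling(3 * blur_sigma),
                      sd = blur_sigma)
    k <- k / sum(k)
    vals <- .conv_sep3(vals, k)
  }
  density_grid(origin = c(g[1], g[1], g[1]), spacing = rep(voxel, 3),
               values = vals)
}

## separable 3-D convolution with a 1-D kernel (zero padding)
.conv_sep3 <- function(a, k) {
  conv1 <- function(v) {
    out <- stats::filter(c(rep(0, length(k)), v, rep(0, length(k))), k,
                         sides = 2)
    out[(length(k) + 1):(length(k) + length(v))]
  }
  d <- dim(a)
  for (ax in 1:3) {
    a <- apply(a, setdiff(1:3, ax), conv1)
    ## apply returns the worked margin first; rotate dims back
    a <- aperm(array(a, dim = c(d[ax], d[setdiff(1:3, ax)])),
               order(c(ax, setdiff(1:3, ax))))
  }
  a
}
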