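# Independent oracles and small fixture builders shared across the tests.

# Circumradius by least-squares equidistance: solve for the center c such
# that |c - p_i| is equal for all four vertices (row-reduced linear system),
# fully independent of the closed-form cross-product route in the package.
oracle_circumradius <- function(p) {
  A <- 2 * (p[2:4, , drop = FALSE] -
              matrix(p[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
  ctr <- qr.solve(A, b)
  sqrt(sum((ctr - p[1, ])^2))
}

# Brute-force Delaunay: a 4-subset is a Delaunay tetrahedron iff its
# circumsphere contains no other point strictly inside.  O(n^5); only for
# tiny general-position clouds.
oracle_delaunay <- function(coords, tol = 1e-9) {
  n <- nrow(coords)
  combs <- utils::combn(n, 4)
  keep <- list()
  for (j in seq_len(ncol(combs))) {
    idx <- combs[, j]
    p <- coords[idx, , drop = FALSE]
    A <- 2 * (p[2:4, ] - matrix(p[1, ], 3, 3, byrow = TRUE))
    if (abs(det(A)) < 1e-10) next
    ctr <- solve(A, rowSums(p[2:4, ]^2) - sum(p[1, ]^2))
    r <- sqrt(sum((ctr - p[1, ])^2))
    others <- setdiff(seq_len(n), idx)
    d <- sqrt(rowSums(sweep(coords[others, , drop = FALSE], 2, ctr)^2))
    if (all(d > r - tol)) keep[[length(keep) + 1L]] <- sort(idx)
  }
  do.call(rbind, keep)
}

# Convex-hull volume via an independent backend (Qhull through scipy's
# ConvexHull, a different code path from the Delaunay filter under test).
oracle_hull_volume <- function(coords) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.table(coords, f, row.names = FALSE, col.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from scipy.spatial import ConvexHull; ",
    "print(repr(ConvexHull(np.loadtxt('", f, "')).volume))"))),
    stdout = TRUE)
  as.numeric(out[length(out)])
}

# Gauss-quadrature evaluation of the element stiffness integral
# int B' C B dV.  B is constant over a linear tetrahedron, so a one-point
# rule is exact; the oracle builds B from independently computed
# shape-function gradients (finite differences of the barycentric
# interpolant) rather than reusing the package's algebra.
oracle_element_stiffness <- function(xyz, lambda, mu, h = 1e-6) {
  interp_grad <- function(vertex) {
    # gradient of shape function `vertex` by central differences at centroid
    centroid <- colMeans(xyz)
    shape_at <- function(pt) {
      A <- cbind(1, xyz)
      as.numeric(solve(t(A), c(1, pt)))[vertex]
    }
    vapply(1:3, function(d) {
      e <- numeric(3); e[d] <- h
      (shape_at(centroid + e) - shape_at(centroid - e)) / (2 * h)
    }, numeric(1))
  }
  G <- vapply(1:4, interp_grad, numeric(3))
  B <- matrix(0, 6, 12)
  for (j in 1:4) {
    c0 <- 3 * (j - 1)
    B[1, c0 + 1] <- G[1, j]; B[2, c0 + 2] <- G[2, j]; B[3, c0 + 3] <- G[3, j]
    B[4, c0 + 1] <- G[2, j]; B[4, c0 + 2] <- G[1, j]
    B[5, c0 + 2] <- G[3, j]; B[5, c0 + 3] <- G[2, j]
    B[6, c0 + 1] <- G[3, j]; B[6, c0 + 3] <- G[1, j]
  }
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3))); C[1:3, 1:3] <- C[1:3, 1:3] + lambda
  V <- abs(det(cbind(1, xyz))) / 6
  V * t(B) %*% C %*% B
}

# Monte-Carlo estimate of the consistent-mass entries rho * int phi_i phi_j
# over a tetrahedron, sampling uniform barycentric points.
oracle_element_mass <- function(xyz, rho, n = 2e5) {
  w <- matrix(stats::rexp(4 * n), ncol = 4)
  w <- w / rowSums(w)                      # uniform over the simplex
  V <- abs(det(cbind(1, xyz))) / 6
  rho * V * crossprod(w) / n
}

# Toy 10-residue PDB with altloc pair, a hydrogen, and two assembly
# operators (identity + a 180-degree rotation about z with translation).
write_toy_pdb <- function(path, n_res = 10) {
  mk <- function(i, elety, resno, alt, occ, x, elem = "C")
    sprintf(
      "ATOM  %5d %4s%sALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, formatC(elety, width = -4), alt, resno, x, resno * 1.3, 0.5, occ,
      20 + resno, elem)
  biomt <- c(
    "REMARK 350   BIOMT1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 350   BIOMT2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 350   BIOMT1   2 -1.000000  0.000000  0.000000       30.00000",
    "REMARK 350   BIOMT2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 350   BIOMT3   2  0.000000  0.000000  1.000000        0.00000")
  at <- c(mk(1, " N  ", 1, " ", 1, 0.0, "N"),
          mk(2, " CA ", 1, "A", 0.4, 1.0),
          mk(3, " CA ", 1, "B", 0.6, 1.2),
          mk(4, " C  ", 1, " ", 1, 2.0),
          mk(5, " O  ", 1, " ", 1, 2.5, "O"),
          mk(6, " H  ", 1, " ", 1, 2.7, "H"))
  for (r in 2:n_res) at <- c(at, mk(10 + r, " CA ", r, " ", 1, r * 3.0))
  writeLines(c(biomt, at, "END"), path)
  path
}

# A jittered random cloud in general position (fixed seed per call site).
random_cloud <- function(n, seed, scale = 5) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
}
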