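## Finite-element assembly for isotropic linear elasticity on linear
## (constant-strain) tetrahedra.

#' Lame parameters from Young's modulus and Poisson ratio
#'
#' `lambda = nu E / ((1 + nu)(1 - 2 nu))`, `mu = E / (2 (1 + nu))`.
#'
#' @param E Young's modulus (kcal mol^-1 A^-3; > 0).
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @return Named list with `lambda` and `mu`.
#' @export
#' @examples
#' lame_parameters(1, 0.25)  # lambda = mu = 0.4
lame_parameters <- function(E, nu) {
  if (E <= 0) stop("Young's modulus must be positive")
  if (nu < 0 || nu >= 0.5)
    stop("Poisson ratio must lie in [0, 0.5); the incompressible limit ",
         "nu = 0.5 is singular")
  list(lambda = nu * E / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' Elastic material parameters
#'
#' Material model of the solid: Young's modulus `E`, Poisson ratio `nu`
#' (default 0.3, the value commonly adopted for proteins), derived Lame
#' parameters, and a uniform mass density `rho` (amu A^-3).  When `rho` is
#' NULL, [assemble()] derives it from the node masses and the solid volume
#' so that the model's total mass equals the molecule's mass.
#'
#' @param E Young's modulus, kcal mol^-1 A^-3.  The stiffness matrix is
#'   strictly proportional to `E`, so modes can be computed at `E = 1` and
#'   rescaled after calibration.
#' @param nu Poisson ratio.
#' @param rho Uniform density (amu A^-3) or NULL.
#' @return An `elastic_params` object.
#' @export
elastic_params <- function(E = 1, nu = 0.3, rho = NULL) {
  lm <- lame_parameters(E, nu)
  if (!is.null(rho) && rho <= 0) stop("density must be positive")
  structure(list(E = E, nu = nu, lambda = lm$lambda, mu = lm$mu, rho = rho),
            class = "elastic_params")
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf(
    "elastic_params: E = %g kcal/mol/A^3 (%.3g GPa), nu = %g, rho = %s\n",
    x$E, x$E * .kcalmolA3_GPa, x$nu,
    if (is.null(x$rho)) "from node masses" else format(x$rho)))
  invisible(x)
}

## 6x6 isotropic elasticity matrix in Voigt order (xx,yy,zz,xy,yz,zx)
.voigt_C <- function(lambda, mu) {
  C <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  C[1:3, 1:3] <- C[1:3, 1:3] + lambda
  C
}

## Shape-function gradients and volume of one tet (rows = vertices).
.tet_grads <- function(xyz) {
  A <- cbind(1, xyz)
  d <- det(A)
  if (abs(d) < 1e-12) stop("degenerate tetrahedron")
  list(grads = solve(A)[2:4, , drop = FALSE],  # 3 x 4: d(phi_j)/d(x,y,z)
       volume = abs(d) / 6)
}

#' Element stiffness matrix of a linear tetrahedron
#'
#' Constant-strain tetrahedron: `Ke = V B' C B` with the isotropic elasticity
#' matrix `C(lambda, mu)`.  The 12 degrees of freedom are ordered
#' (x1,y1,z1, ..., x4,y4,z4).
#'
#' @param xyz 4 x 3 matrix of vertex coordinates.
#' @param lambda,mu Lame parameters.
#' @return Symmetric positive-semidefinite 12 x 12 matrix with exactly six
#'   zero eigenvalues (rigid-body motions).
#' @export
element_stiffness <- function(xyz, lambda, mu) {
  g <- .tet_grads(as.matrix(xyz))
  B <- matrix(0, 6, 12)
  for (j in 1:4) {
    c0 <- 3 * (j - 1)
    bx <- g$grads[1, j]; by <- g$grads[2, j]; bz <- g$grads[3, j]
    B[1, c0 + 1] <- bx
    B[2, c0 + 2] <- by
    B[3, c0 + 3] <- bz
    B[4, c0 + 1] <- by; B[4, c0 + 2] <- bx
    B[5, c0 + 2] <- bz; B[5, c0 + 3] <- by
    B[6, c0 + 1] <- bz; B[6, c0 + 3] <- bx
  }
  Ke <- g$volume * crossprod(B, .voigt_C(lambda, mu) %*% B)
  (Ke + t(Ke)) / 2
}

#' Consistent element mass matrix (scalar-field block)
#'
#' For a linear tetrahedron the consistent mass matrix over the four scalar
#' shape functions is `rho V / 20 * (1 + delta_ij)`; each row sums to
#' `rho V / 4` and the total equals the element mass `rho V`.  The full
#' 12 x 12 block is this matrix Kronecker the 3 x 3 identity.
#'
#' @param xyz 4 x 3 matrix of vertex coordinates.
#' @param rho Density (amu A^-3).
#' @return 4 x 4 matrix.
#' @export
element_mass <- function(xyz, rho) {
  g <- .tet_grads(as.matrix(xyz))
  rho * g$volume / 20 * (matrix(1, 4, 4) + diag(4))
}

#' Assemble global stiffness and mass matrices
#'
#' Assembles the sparse symmetric `3N x 3N` stiffness matrix `K`
#' (kcal mol^-1 A^-2) and mass matrix `M` (amu) over all tetrahedra of the
#' mesh.  The scalar `N x N` consistent mass matrix is expanded to
#' `3N x 3N` by a Kronecker product with the 3 x 3 identity; degrees of
#' freedom are interleaved per node (x1,y1,z1,x2,...).  `K` scales linearly
#' with `E` at fixed `nu` and annihilates the six rigid-body motions of a
#' connected mesh.
#'
#' When `params$rho` is NULL the uniform density is taken as
#' (total node mass)/(solid volume), so that the model's total mass equals
#' the molecule's mass and absolute frequencies are meaningful.
#'
#' @param mesh A `tet_mesh` from [build_alpha_shape()].
#' @param params An [elastic_params()] object.
#' @param mass `"consistent"` (default, the finite-element mass matrix) or
#'   `"lumped"` (row-sum diagonal lumping, for sensitivity checks).
#' @return A `global_system`: sparse `K`, `M`, the scalar mass matrix
#'   `Ms` (N x N), `n_nodes`, `params`, `rho`, `masses` and the source
#'   `mesh`.
#' @export
assemble <- function(mesh, params = elastic_params(),
                     mass = c("consistent", "lumped")) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(params, "elastic_params"))
  mass <- match.arg(mass)
  nodes <- mesh$nodes
  tets <- mesh$tets
  n <- nrow(nodes)
  nt <- nrow(tets)
  used <- unique(as.vector(tets))
  if (length(used) < n)
    warning(n - length(used), " node(s) are not part of any tetrahedron; ",
            "their degrees of freedom carry no stiffness")
  rho <- params$rho
  if (is.null(rho)) {
    total_mass <- if (!is.null(mesh$masses)) sum(mesh$masses) else 110 * n
    rho <- total_mass / sum(mesh$volumes)
  }

  ## stiffness triplets: 144 entries per element
  ii <- integer(144L * nt); jj <- integer(144L * nt); xx <- numeric(144L * nt)
  ## scalar mass triplets: 16 per element
  mi <- integer(16L * nt); mj <- integer(16L * nt); mx <- numeric(16L * nt)
  m4 <- (matrix(1, 4, 4) + diag(4)) / 20
  for (e in seq_len(nt)) {
    vid <- tets[e, ]
    Ke <- element_stiffness(nodes[vid, , drop = FALSE],
                            params$lambda, params$mu)
    dof <- as.vector(t(cbind(3 * vid - 2, 3 * vid - 1, 3 * vid)))
    o <- 144L * (e - 1L)
    ii[o + seq_len(144L)] <- rep(dof, times = 12L)
    jj[o + seq_len(144L)] <- rep(dof, each = 12L)
    xx[o + seq_len(144L)] <- as.vector(Ke)
    om <- 16L * (e - 1L)
    mi[om + seq_len(16L)] <- rep(vid, times = 4L)
    mj[om + seq_len(16L)] <- rep(vid, each = 4L)
    mx[om + seq_len(16L)] <- as.vector(rho * mesh$volumes[e] * m4)
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3 * n, 3 * n))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  Ms <- Matrix::sparseMatrix(i = mi, j = mj, x = mx, dims = c(n, n))
  Ms <- Matrix::forceSymmetric((Ms + Matrix::t(Ms)) / 2)
  if (mass == "lumped")
    Ms <- Matrix::Diagonal(n, Matrix::rowSums(Ms))
  M <- Matrix::kronecker(Ms, Matrix::Diagonal(3))
  structure(list(K = K, M = M, Ms = Ms, n_nodes = n, params = params,
                 rho = rho, masses = mesh$masses, mesh = mesh,
                 mass_type = mass),
            class = "global_system")
}

#' @export
print.global_system <- function(x, ...) {
  cat(sprintf(
    "global_system: %d nodes (%d DOF), E = %g, nu = %g, rho = %.4g amu/A^3, %s mass\n",
    x$n_nodes, 3 * x$n_nodes, x$params$E, x$params$nu, x$rho, x$mass_type))
  invisible(x)
}

#' Export stiffness/mass matrices in Matrix Market format
#'
#' Debug helper: writes `K` and `M` of an assembled system as MatrixMarket
#' files next to `basename`.
#'
#' @param system A `global_system`.
#' @param basename Path prefix; files `<basename>-K.mtx`, `<basename>-M.mtx`.
#' @return Invisibly, the two file paths.
#' @export
export_system_matrices <- function(system, basename) {
  kf <- paste0(basename, "-K.mtx"); mf <- paste0(basename, "-M.mtx")
  Matrix::writeMM(as(system$K, "generalMatrix"), kf)
  Matrix::writeMM(as(system$M, "generalMatrix"), mf)
  invisible(c(kf, mf))
}
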