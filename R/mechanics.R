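## Linear static response: fixed nodes, applied forces, prescribed
## displacements, and the indentation-stiffness surrogate.

#' Linear static solve with fixed nodes and applied forces
#'
#' Solves `K u = f` on the free degrees of freedom with all three DOFs of
#' `fixed_nodes` clamped (and, optionally, prescribed non-zero displacements
#' on further nodes).  Reaction forces are recovered at constrained nodes;
#' in equilibrium applied and reaction forces sum to zero.
#'
#' @param system A `global_system`.
#' @param fixed_nodes Integer node indices clamped to zero displacement.
#' @param forces Applied forces: N x 3 matrix (kcal mol^-1 A^-1), or a data
#'   frame with columns `node`, `fx`, `fy`, `fz`.
#' @param prescribed Optional data frame with columns `node`, `ux`, `uy`,
#'   `uz` of prescribed displacements (A).
#' @return A `deformation_result`: `displacements` (N x 3, A), `reactions`
#'   (data frame for constrained nodes), `fixed_nodes`, `total_applied`,
#'   `total_reaction`.
#' @export
static_solve <- function(system, fixed_nodes, forces = NULL,
                         prescribed = NULL) {
  stopifnot(inherits(system, "global_system"))
  n <- system$n_nodes
  f <- numeric(3L * n)
  if (!is.null(forces)) {
    if (is.data.frame(forces)) {
      idx <- as.integer(forces$node)
      f[3 * idx - 2] <- forces$fx
      f[3 * idx - 1] <- forces$fy
      f[3 * idx] <- forces$fz
    } else {
      fm <- as.matrix(forces)
      stopifnot(nrow(fm) == n, ncol(fm) == 3)
      f <- as.vector(t(fm))
    }
  }
  u <- numeric(3L * n)
  cons_nodes <- unique(as.integer(fixed_nodes))
  if (!is.null(prescribed)) {
    pn <- as.integer(prescribed$node)
    if (length(intersect(pn, cons_nodes)))
      stop("prescribed and fixed node sets must be disjoint")
    u[3 * pn - 2] <- prescribed$ux
    u[3 * pn - 1] <- prescribed$uy
    u[3 * pn] <- prescribed$uz
    cons_nodes <- c(cons_nodes, pn)
  }
  if (!length(cons_nodes)) stop("at least one constrained node is required")
  if (any(f[.node_dofs(cons_nodes)] != 0))
    stop("fixed and loaded node sets must be disjoint")
  cdof <- .node_dofs(cons_nodes)
  fdof <- setdiff(seq_len(3L * n), cdof)
  K <- system$K
  rhs <- f[fdof] - as.numeric(K[fdof, cdof, drop = FALSE] %*% u[cdof])
  uf <- tryCatch(
    as.numeric(Matrix::solve(
      Matrix::Cholesky(Matrix::forceSymmetric(K[fdof, fdof]), LDL = FALSE,
                       perm = TRUE),
      rhs)),
    error = function(e)
      stop("reduced stiffness is singular: the constraints leave a ",
           "rigid-body motion (or a disconnected piece) free", call. = FALSE))
  u[fdof] <- uf
  resid <- as.numeric(K %*% u) - f
  reactions <- matrix(resid[cdof], ncol = 3L, byrow = TRUE)
  disp <- matrix(u, ncol = 3L, byrow = TRUE)
  structure(list(displacements = disp,
                 reactions = data.frame(node = cons_nodes,
                                        rx = reactions[, 1],
                                        ry = reactions[, 2],
                                        rz = reactions[, 3]),
                 fixed_nodes = cons_nodes,
                 total_applied = colSums(matrix(f, ncol = 3, byrow = TRUE)),
                 total_reaction = colSums(reactions),
                 forces = f, u = u, system = system),
            class = "deformation_result")
}

.node_dofs <- function(nodes) as.vector(t(cbind(3 * nodes - 2,
                                                3 * nodes - 1, 3 * nodes)))

#' @export
print.deformation_result <- function(x, ...) {
  cat(sprintf(
    "deformation_result: max |u| = %.4g A, %d constrained nodes, force balance %.2e\n",
    max(sqrt(rowSums(x$displacements^2))), length(x$fixed_nodes),
    max(abs(x$total_applied + x$total_reaction))))
  invisible(x)
}

#' Per-node deformation extents along and perpendicular to an axis
#'
#' For each node, the absolute displacement along the chosen axis and the
#' in-plane magnitude perpendicular to it, as used to contrast axial versus
#' lateral response under a vertical load.
#'
#' @param result A `deformation_result`.
#' @param axis `"x"`, `"y"` or `"z"` (default `"z"`).
#' @return Data frame with `extent_axis`, `extent_plane`; the maxima are in
#'   attributes `max_axis`, `max_plane`.
#' @export
deformation_extents <- function(result, axis = c("z", "x", "y")) {
  stopifnot(inherits(result, "deformation_result"))
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  u <- result$displacements
  out <- data.frame(extent_axis = abs(u[, ai]),
                    extent_plane = sqrt(rowSums(u[, -ai, drop = FALSE]^2)))
  attr(out, "max_axis") <- max(out$extent_axis)
  attr(out, "max_plane") <- max(out$extent_plane)
  out
}

#' Indentation stiffness surrogate (AFM tip pressing on the solid)
#'
#' Linear small-indentation surrogate for a rigid-sphere indentation: the
#' tip (radius `tip_radius`) is placed tangent to the topmost node along
#' `tip_axis`, pushed in by `depth`, and every surface node inside the
#' spherical footprint receives the prescribed displacement of the sphere
#' surface; base nodes (lowest `base_fraction` of the extent) are fixed.
#' The total reaction force along the axis divided by the depth and by the
#' Young's modulus gives the indentation stiffness per unit modulus,
#' `kappa_cal`, which is independent of the `E` actually used since the
#' stiffness matrix is proportional to `E`.
#'
#' This is a linearized stand-in for a full nonlinear contact simulation,
#' valid in the small-indentation limit.
#'
#' @param mesh A `tet_mesh`.
#' @param params [elastic_params()] used for the assembly.
#' @param tip_radius Sphere radius (A).
#' @param tip_axis `"z"`, `"x"` or `"y"`.
#' @param depth Indentation depth (A), default 1.
#' @param base_fraction Fraction of the axial extent clamped at the bottom,
#'   default 0.1.
#' @return List with `kappa_cal_A` (A of stiffness per unit E, i.e.
#'   (kcal mol^-1 A^-2)/(kcal mol^-1 A^-3)), `kappa_cal_nm` (same in nm:
#'   stiffness in nN/nm per unit E in GPa), `force`, `depth`,
#'   `contact_nodes`, `fixed_nodes`.
#' @export
indentation_stiffness <- function(mesh, params = elastic_params(),
                                  tip_radius, tip_axis = c("z", "x", "y"),
                                  depth = 1, base_fraction = 0.1) {
  stopifnot(inherits(mesh, "tet_mesh"), tip_radius > 0, depth > 0)
  tip_axis <- match.arg(tip_axis)
  ai <- match(tip_axis, c("x", "y", "z"))
  nodes <- mesh$nodes
  used <- sort(unique(as.vector(mesh$tets)))
  zl <- nodes[used, ai]
  zmax <- max(zl); zmin <- min(zl)
  apex_node <- used[which.max(zl)]
  center <- nodes[apex_node, ]
  center[ai] <- zmax + tip_radius
  ## after pushing down by `depth`, sphere surface height at lateral r:
  ##   z_s(r) = (zmax - depth) + tip_radius - sqrt(tip_radius^2 - r^2)
  lat <- sqrt(rowSums(sweep(nodes[used, -ai, drop = FALSE], 2,
                            center[-ai])^2))
  zs <- (zmax - depth) + tip_radius -
    sqrt(pmax(tip_radius^2 - lat^2, 0))
  contact <- used[lat < tip_radius & nodes[used, ai] > zs]
  push <- pmin(0, zs - nodes[used, ai])[match(contact, used)]
  if (!length(contact)) stop("empty contact set: tip does not touch the mesh")
  base <- used[zl <= zmin + base_fraction * (zmax - zmin)]
  base <- setdiff(base, contact)
  if (!length(base)) stop("no base nodes to fix; increase base_fraction")
  pres <- data.frame(node = contact, ux = 0, uy = 0, uz = 0)
  pres[[c("ux", "uy", "uz")[ai]]] <- push
  sys <- assemble(mesh, params)
  sol <- static_solve(sys, fixed_nodes = base, prescribed = pres)
  Fax <- sum(sol$reactions[match(contact, sol$reactions$node),
                           c("rx", "ry", "rz")[ai]])
  kA <- abs(Fax) / depth / params$E          # A per unit E (working units)
  list(kappa_cal_A = kA, kappa_cal_nm = kA / 10,
       force = abs(Fax), depth = depth,
       contact_nodes = contact, fixed_nodes = base, solution = sol)
}

#' Young's modulus from AFM stiffness and computed indentation slope
#'
#' `E = k_exp / kappa_cal`: the measured capsid stiffness (nN/nm) divided by
#' the computed indentation stiffness per unit modulus (nm per unit E in
#' GPa, since nN/nm^2 = GPa) gives the material's Young's modulus in GPa.
#'
#' @param kappa_cal Computed slope, nm per unit E (GPa).
#' @param k_exp Measured AFM stiffness, nN/nm.
#' @return Young's modulus in GPa.
#' @export
#' @examples
#' young_from_afm(kappa_cal = 0.65, k_exp = 0.15)  # ~0.23 GPa
young_from_afm <- function(kappa_cal, k_exp) {
  if (kappa_cal <= 0 || k_exp <= 0)
    stop("kappa_cal and k_exp must be positive")
  k_exp / kappa_cal
}
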