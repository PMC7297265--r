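## Alpha-shape solids: Delaunay tetrahedralization filtered by circumradius.

#' Circumradius of a tetrahedron
#'
#' Radius of the unique sphere through the four vertices.  The circumcenter
#' is obtained from the linear system expressing equidistance to all four
#' points.
#'
#' @param p0,p1,p2,p3 Numeric length-3 vertex coordinates.
#' @return Circumradius (same length unit as the input).
#' @export
#' @examples
#' circumradius(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1))  # sqrt(3)/2
circumradius <- function(p0, p1, p2, p3) {
  A <- 2 * rbind(p1 - p0, p2 - p0, p3 - p0)
  if (abs(det(A)) < 1e-12 * max(1, max(abs(A)))^3)
    stop("degenerate tetrahedron: vertices are (near-)coplanar")
  b <- c(sum(p1^2) - sum(p0^2), sum(p2^2) - sum(p0^2), sum(p3^2) - sum(p0^2))
  ctr <- solve(A, b)
  sqrt(sum((ctr - p0)^2))
}

## Vectorized volumes and circumradii for a T x 4 tet index matrix.
## Uses the cross-product closed form
##   u = (|a|^2 (b x c) + |b|^2 (c x a) + |c|^2 (a x b)) / (2 a.(b x c)),
## R = |u|, V = |a.(b x c)|/6, with a,b,c edge vectors from vertex 0.
tet_geometry <- function(coords, tets) {
  p0 <- coords[tets[, 1], , drop = FALSE]
  a <- coords[tets[, 2], , drop = FALSE] - p0
  b <- coords[tets[, 3], , drop = FALSE] - p0
  c_ <- coords[tets[, 4], , drop = FALSE] - p0
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bc <- cross(b, c_); ca <- cross(c_, a); ab <- cross(a, b)
  det6 <- rowSums(a * bc)            # 6V signed
  vol <- abs(det6) / 6
  num <- rowSums(a^2) * bc + rowSums(b^2) * ca + rowSums(c_^2) * ab
  r <- rep(Inf, nrow(tets))
  ok <- abs(det6) > 0
  r[ok] <- sqrt(rowSums((num[ok, , drop = FALSE] /
                           (2 * det6[ok]))^2))
  list(volume = vol, circumradius = r)
}

## Deterministic symbolic-style perturbation.  Exactly degenerate inputs
## (lattices: cospherical and coplanar point groups) make the Delaunay
## tetrahedralization non-unique and circumradii of flat cells ill-defined.
## A fixed, input-independent jitter sequence (integer-hash LCG, amplitude
## 1e-8 of the bounding-box extent) restores general position; the
## triangulation and circumradius *filtering* are evaluated on the jittered
## coordinates (whose values are generic-perturbation limits of the
## degenerate ones), while volumes, nodes and all downstream physics use
## the original coordinates exactly.
.jitter_coords <- function(coords, eps = 1e-8) {
  n3 <- length(coords)
  u <- (as.double((seq_len(n3) * 2654435761) %% 2^32)) / 2^32
  scale <- max(apply(coords, 2, function(x) diff(range(x))), 1)
  coords + matrix((u - 0.5) * eps * scale, ncol = 3L)
}

## Delaunay cells with jittered-coordinate circumradii and exact volumes.
.alpha_complex <- function(coords) {
  jit <- .jitter_coords(coords)
  tets <- delaunay_tetrahedra(jit)
  list(tets = tets,
       r = tet_geometry(jit, tets)$circumradius,
       vol = tet_geometry(coords, tets)$volume,
       jit = jit)
}

## coverage for the critical alpha counts only positive-volume cells: a
## node whose sole cover is a degenerate gluing cell would carry no mass
## or stiffness in the finite-element step
.critical_alpha_of <- function(ac, n_points, sliver_tol) {
  solid <- ac$vol >= sliver_tol
  .critical_alpha_from(ac$tets[solid, , drop = FALSE], ac$r[solid],
                       n_points)
}

#' Build the alpha-shape tetrahedral solid of a point set
#'
#' Computes the Delaunay tetrahedralization of the points and keeps only the
#' tetrahedra whose circumsphere radii are less than or equal to `alpha`.
#' The nodes of the returned mesh are exactly the input coordinates; no new
#' nodes are created.
#'
#' Exactly degenerate cells (zero volume, which arise for lattice-like
#' inputs where several points are cospherical and coplanar) are retained
#' in the complex for boundary and connectivity purposes -- they glue their
#' neighbours together, which keeps the boundary surface watertight -- but
#' cells with volume below `sliver_tol` are excluded from the element list
#' used for volume and finite-element assembly, where a zero-volume cell
#' would be singular.  Cospherical ties are resolved by a deterministic
#' internal perturbation; results can differ between triangulation backends
#' only in such zero-measure cases.
#'
#' With `alpha = NULL` the critical alpha is used: the smallest value whose
#' shape encloses all the points (see [critical_alpha()]).
#'
#' @param points A [point_set] or N x 3 coordinate matrix.
#' @param alpha Filter radius in Angstrom (`Inf` keeps the full Delaunay
#'   tetrahedralization), or NULL for the critical alpha.
#' @param sliver_tol Volume below which a kept cell is excluded from the
#'   finite-element set (A^3), default 1e-9.
#' @return A `tet_mesh`: `nodes` (the input coordinates), `tets` (T x 4
#'   node indices of the positive-volume elements), `volumes`,
#'   `circumradii`, `tets_complex` (including degenerate gluing cells),
#'   `alpha`, per-node `masses` when the input was a [point_set], and the
#'   unfiltered `delaunay` cell list (used by [alpha_for_volume()]).
#' @export
build_alpha_shape <- function(points, alpha = NULL, sliver_tol = 1e-9) {
  coords <- .as_coords(points)
  if (!is.null(alpha) && (!is.numeric(alpha) || alpha <= 0))
    stop("`alpha` must be positive (or NULL for the critical alpha)")
  ac <- .alpha_complex(coords)
  if (is.null(alpha))
    alpha <- .critical_alpha_of(ac, nrow(coords), sliver_tol)
  sel <- ac$r <= alpha
  fem <- sel & ac$vol >= sliver_tol
  if (!any(fem))
    stop("empty alpha shape: no tetrahedron has circumradius <= ",
         format(alpha))
  structure(list(nodes = coords,
                 tets = ac$tets[fem, , drop = FALSE],
                 volumes = ac$vol[fem],
                 circumradii = ac$r[fem],
                 tets_complex = ac$tets[sel, , drop = FALSE],
                 alpha = alpha,
                 masses = if (inherits(points, "point_set")) points$masses,
                 nodes_jittered = ac$jit,
                 delaunay = list(tets = ac$tets, volumes = ac$vol,
                                 circumradii = ac$r)),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf(
    "tet_mesh: %d nodes (%d used), %d tetrahedra, alpha = %.4g A, volume = %.6g A^3\n",
    nrow(x$nodes), length(unique(as.vector(x$tets))), nrow(x$tets),
    x$alpha, sum(x$volumes)))
  invisible(x)
}

## smallest alpha covering all N points, given cells + circumradii
.critical_alpha_from <- function(tets, r, n_points) {
  cover <- tapply(rep(r, 4L), as.vector(tets), min)
  covered <- as.integer(names(cover))
  if (length(covered) < n_points)
    warning(n_points - length(covered),
            " point(s) belong to no proper Delaunay cell and cannot be ",
            "enclosed at any alpha")
  max(cover)
}

#' Critical alpha of a point set
#'
#' The smallest alpha value for which the alpha shape encloses all input
#' points, i.e. every point is a vertex of at least one kept tetrahedron.
#' Since the kept set only changes at the (finite) circumradius values of
#' the Delaunay cells, the result is the largest over points of the smallest
#' incident circumradius.
#'
#' @inheritParams build_alpha_shape
#' @return Critical alpha in Angstrom.
#' @export
critical_alpha <- function(points, sliver_tol = 1e-9) {
  coords <- .as_coords(points)
  ac <- .alpha_complex(coords)
  .critical_alpha_of(ac, nrow(coords), sliver_tol)
}

#' Total volume of an alpha-shape solid
#'
#' @param mesh A `tet_mesh`.
#' @return Sum of tetrahedron volumes in A^3.
#' @export
shape_volume <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  sum(mesh$volumes)
}

#' Boundary surface of a tetrahedral solid
#'
#' The boundary consists of the triangular facets that belong to exactly one
#' kept tetrahedron, oriented outward (the normal points away from the
#' opposite vertex of the owning tetrahedron).
#'
#' @param mesh A `tet_mesh`.
#' @return A `tri_mesh` with fields `nodes` (the full node array),
#'   `triangles` (F x 3, outward-oriented) and `surface_nodes` (indices of
#'   nodes on the boundary).
#' @export
boundary_surface <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  tets <- if (!is.null(mesh$tets_complex)) mesh$tets_complex else mesh$tets
  ## the 4 facets of each tet, with the opposite vertex alongside
  fidx <- rbind(c(2, 3, 4, 1), c(1, 3, 4, 2), c(1, 2, 4, 3), c(1, 2, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(k)
    cbind(tets[, fidx[k, 1]], tets[, fidx[k, 2]], tets[, fidx[k, 3]],
          tets[, fidx[k, 4]])))
  skey <- t(apply(faces[, 1:3, drop = FALSE], 1L, sort))
  n <- nrow(mesh$nodes)
  key <- (skey[, 1] - 1) + n * ((skey[, 2] - 1) + n * (skey[, 3] - 1))
  cnt <- table(key)
  boundary <- faces[key %in% as.numeric(names(cnt)[cnt == 1L]), ,
                    drop = FALSE]
  ## outward orientation: flip when normal . (opposite - a) > 0; evaluated
  ## on the (deterministically jittered) general-position coordinates so
  ## that faces owned by a degenerate gluing cell still orient reliably
  geo_nodes <- if (!is.null(mesh$nodes_jittered)) mesh$nodes_jittered
               else mesh$nodes
  a <- geo_nodes[boundary[, 1], , drop = FALSE]
  e1 <- geo_nodes[boundary[, 2], , drop = FALSE] - a
  e2 <- geo_nodes[boundary[, 3], , drop = FALSE] - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  inward <- rowSums(nrm * (geo_nodes[boundary[, 4], , drop = FALSE] - a)) > 0
  tri <- boundary[, 1:3, drop = FALSE]
  tri[inward, 2:3] <- tri[inward, 3:2]
  structure(list(nodes = mesh$nodes, triangles = tri,
                 surface_nodes = sort(unique(as.vector(tri)))),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d triangles over %d surface nodes\n",
              nrow(x$triangles), length(x$surface_nodes)))
  invisible(x)
}

#' Surface area of a triangle mesh
#' @param surface A `tri_mesh`.
#' @return Total area (A^2).
#' @export
surface_area <- function(surface) {
  stopifnot(inherits(surface, "tri_mesh"))
  a <- surface$nodes[surface$triangles[, 1], , drop = FALSE]
  e1 <- surface$nodes[surface$triangles[, 2], , drop = FALSE] - a
  e2 <- surface$nodes[surface$triangles[, 3], , drop = FALSE] - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(nrm^2))) / 2
}

#' Connected components of a tetrahedral solid
#'
#' Partitions the kept tetrahedra into connected components, by default
#' through shared vertices (two tetrahedra are connected when they share at
#' least one node); stricter face-sharing connectivity is available as an
#' option.  Components are returned ordered by node count, largest first.
#'
#' @param mesh A `tet_mesh`.
#' @param by `"vertex"` (default) or `"face"`.
#' @return List of `tet_mesh` objects (each retains the full node array).
#' @export
connected_components <- function(mesh, by = c("vertex", "face")) {
  stopifnot(inherits(mesh, "tet_mesh"))
  by <- match.arg(by)
  tets <- if (!is.null(mesh$tets_complex)) mesh$tets_complex else mesh$tets
  nt <- nrow(tets)
  if (by == "vertex") {
    ## bipartite union through nodes: edges node -> owning tet
    edges <- rbind(as.vector(t(tets)),
                   rep(nrow(mesh$nodes) + seq_len(nt), each = 4L))
    g <- igraph::make_graph(edges, n = nrow(mesh$nodes) + nt,
                            directed = FALSE)
    comp <- igraph::components(g)$membership[nrow(mesh$nodes) + seq_len(nt)]
  } else {
    fidx <- utils::combn(4L, 3L)
    faces <- do.call(rbind, lapply(seq_len(ncol(fidx)), function(k)
      t(apply(tets[, fidx[, k], drop = FALSE], 1L, sort))))
    n <- nrow(mesh$nodes)
    key <- (faces[, 1] - 1) + n * ((faces[, 2] - 1) + n * (faces[, 3] - 1))
    owner <- rep(seq_len(nt), 4L)
    sp <- split(owner, key)
    shared <- sp[lengths(sp) == 2L]
    edges <- if (length(shared)) do.call(rbind, shared) else
      matrix(integer(), 0, 2)
    g <- igraph::make_graph(t(edges), n = nt, directed = FALSE)
    comp <- igraph::components(g)$membership
  }
  ## carry the positive-volume element list into each component by the
  ## component of its first vertex (all four vertices agree by construction)
  node_comp <- rep(NA_integer_, nrow(mesh$nodes))
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    node_comp[unique(as.vector(tets[idx, , drop = FALSE]))] <- cid
  }
  fem_comp <- node_comp[mesh$tets[, 1]]
  pieces <- lapply(sort(unique(comp)), function(cid) {
    ci <- which(comp == cid)
    fi <- which(fem_comp == cid)
    structure(list(nodes = mesh$nodes,
                   tets = mesh$tets[fi, , drop = FALSE],
                   volumes = mesh$volumes[fi],
                   circumradii = mesh$circumradii[fi],
                   tets_complex = tets[ci, , drop = FALSE],
                   alpha = mesh$alpha, masses = mesh$masses,
                   nodes_jittered = mesh$nodes_jittered,
                   delaunay = mesh$delaunay),
              class = "tet_mesh")
  })
  ord <- order(vapply(pieces, function(m)
    length(unique(as.vector(m$tets_complex))), integer(1)),
    decreasing = TRUE)
  pieces[ord]
}

#' Alpha value matching a target solid volume
#'
#' The shape volume is a stepwise non-decreasing function of alpha, jumping
#' only at the circumradius values of the Delaunay cells.  The candidate
#' volumes are therefore enumerated exactly (cumulative sums over cells
#' sorted by circumradius) and the smallest alpha in the plateau whose
#' volume matches the target within `tol` (relative) is returned.  This is
#' the mechanism used to keep a coarse model's volume equal to that of a
#' finer reference model.
#'
#' @inheritParams build_alpha_shape
#' @param target_volume Target solid volume (A^3).
#' @param bracket Optional length-2 alpha range to search within.
#' @param tol Relative volume tolerance, default 0.001 (0.1%).
#' @return Alpha in Angstrom.
#' @export
alpha_for_volume <- function(points, target_volume, bracket = NULL,
                             tol = 0.001, sliver_tol = 1e-9) {
  stopifnot(target_volume > 0)
  coords <- .as_coords(points)
  ac <- .alpha_complex(coords)
  r <- ac$r
  v <- ac$vol
  ord <- order(r)
  r <- r[ord]; v <- cumsum(v[ord])
  ## one candidate alpha per distinct circumradius (plateau start)
  last <- !duplicated(r, fromLast = TRUE)
  cand_a <- r[last]; cand_v <- v[last]
  if (!is.null(bracket)) {
    inb <- cand_a >= bracket[1] & cand_a <= bracket[2]
    cand_a <- cand_a[inb]; cand_v <- cand_v[inb]
  }
  err <- abs(cand_v - target_volume)
  hit <- which(err <= tol * target_volume)
  if (!length(hit))
    stop("target volume ", format(target_volume),
         " not attainable within the bracket: closest achievable is ",
         format(cand_v[which.min(err)]))
  ## best match within the band; smallest alpha on the matching plateau
  best <- hit[which.min(err[hit])]
  cand_a[best]
}
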