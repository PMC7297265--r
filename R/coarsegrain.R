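## Shape-preserving non-uniform coarse-graining: layer-wise surface
## decimation plus matched interior downsampling.

#' Coarse-graining specification
#'
#' @param fraction Target retained fraction per layer, in (0, 1].
#' @param alpha Alpha value (A) used to build each layer's shape.
#' @param n_layers Maximum peeling depth (default Inf: peel until fewer
#'   than four interior points remain).
#' @param seed Integer seed controlling the interior-downsampling
#'   representative choice.
#' @return A `coarsen_spec` object.
#' @export
coarsen_spec <- function(fraction, alpha, n_layers = Inf, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1, alpha > 0, n_layers >= 1)
  structure(list(fraction = fraction, alpha = alpha, n_layers = n_layers,
                 seed = as.integer(seed)), class = "coarsen_spec")
}

#' Simplify a boundary surface, keeping a subset of the original nodes
#'
#' Decimates the triangle mesh by greedy quadric edge collapse down to
#' `fraction` of the original face count, then snaps every decimated vertex
#' back to its nearest original surface node, so the returned nodes are a
#' strict subset of the input points.  (Mesh simplifiers move vertices; the
#' snap-back keeps the "input coordinates are the nodes" property that the
#' solid model relies on.)
#'
#' @param surface A `tri_mesh` from [boundary_surface()].
#' @param fraction Target fraction of faces to keep, in (0, 1].
#' @return Integer vector of retained node indices (into `surface$nodes`);
#'   the decimated triangulation before snapping is in attribute
#'   `decimated` (list with `vertices`, `faces`).
#' @export
reduce_surface <- function(surface, fraction) {
  stopifnot(inherits(surface, "tri_mesh"), fraction > 0, fraction <= 1)
  sn <- surface$surface_nodes
  if (fraction == 1) return(sn)
  V <- surface$nodes[sn, , drop = FALSE]
  F_ <- matrix(match(surface$triangles, sn), ncol = 3L)
  if (round(fraction * nrow(F_)) < 4)
    stop("fraction too small: decimation cannot keep a closed surface ",
         "(fewer than 4 faces requested)")
  dec <- .qem_decimate(V, F_, target_faces = round(fraction * nrow(F_)))
  keep_local <- sort(unique(as.vector(dec$faces)))
  nn <- FNN::get.knnx(V, dec$vertices[keep_local, , drop = FALSE], k = 1)
  out <- sort(unique(sn[nn$nn.index[, 1]]))
  attr(out, "decimated") <- dec
  out
}

## Quadric-error-metric edge collapse, pass-based: in each pass edge costs
## are computed (vectorized), edges are visited in ascending cost order and
## collapsed when vertex-disjoint from earlier collapses in the pass.
## Candidate positions per edge are the two endpoints and the midpoint;
## traversal order and tie-breaks are deterministic.
.qem_decimate <- function(V, F_, target_faces) {
  m <- nrow(V)
  Q <- matrix(0, m, 16)                     # per-vertex 4x4 quadric, row-major
  a <- V[F_[, 1], , drop = FALSE]
  e1 <- V[F_[, 2], , drop = FALSE] - a
  e2 <- V[F_[, 3], , drop = FALSE] - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  l <- sqrt(rowSums(nrm^2)); l[l < 1e-14] <- Inf
  p <- cbind(nrm / l, -rowSums(nrm / l * a))        # plane (n, d) per face
  pa <- rep(1:4, times = 4); pb <- rep(1:4, each = 4)
  Kp <- p[, pa, drop = FALSE] * p[, pb, drop = FALSE]  # f x 16 face quadrics
  for (corner in 1:3) {
    agg <- rowsum(Kp, F_[, corner])
    vids <- as.integer(rownames(agg))
    Q[vids, ] <- Q[vids, ] + agg
  }
  n_faces <- nrow(F_)
  quad_cost <- function(QE, P) {            # e x 16 quadrics, e x 3 points
    PH <- cbind(P, 1)
    cost <- 0
    for (k in 1:16) cost <- cost + PH[, pa[k]] * PH[, pb[k]] * QE[, k]
    cost
  }
  repeat {
    if (n_faces <= target_faces) break
    ed <- rbind(F_[, c(1, 2)], F_[, c(2, 3)], F_[, c(1, 3)])
    ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
    ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
    if (!nrow(ed)) break
    QE <- Q[ed[, 1], , drop = FALSE] + Q[ed[, 2], , drop = FALSE]
    Pu <- V[ed[, 1], , drop = FALSE]; Pw <- V[ed[, 2], , drop = FALSE]
    costs <- cbind(quad_cost(QE, Pu), quad_cost(QE, Pw),
                   quad_cost(QE, (Pu + Pw) / 2))
    pick <- max.col(-costs, ties.method = "first")
    cost <- costs[cbind(seq_len(nrow(ed)), pick)]
    ord <- order(cost, ed[, 1], ed[, 2])
    touched <- logical(m)
    map <- seq_len(m)
    progressed <- FALSE
    for (k in ord) {
      if (n_faces <= target_faces) break
      u <- ed[k, 1]; w <- ed[k, 2]
      if (touched[u] || touched[w]) next
      shared <- sum((F_[, 1] == u | F_[, 2] == u | F_[, 3] == u) &
                      (F_[, 1] == w | F_[, 2] == w | F_[, 3] == w))
      if (n_faces - shared < target_faces && progressed) break
      pos <- switch(pick[k], Pu[k, ], Pw[k, ], (Pu[k, ] + Pw[k, ]) / 2)
      V[u, ] <- pos
      Q[u, ] <- Q[u, ] + Q[w, ]
      map[w] <- u
      touched[u] <- TRUE; touched[w] <- TRUE
      n_faces <- n_faces - shared
      progressed <- TRUE
    }
    if (!progressed) break
    F_ <- matrix(map[F_], ncol = 3L)
    keep <- F_[, 1] != F_[, 2] & F_[, 2] != F_[, 3] & F_[, 1] != F_[, 3]
    F_ <- F_[keep, , drop = FALSE]
    n_faces <- nrow(F_)
  }
  list(vertices = V, faces = F_)
}

#' Deterministic voxel-grid downsampling of a point set
#'
#' Bins points on a cubic grid and keeps one representative per occupied
#' voxel; the grid pitch is searched so that the retained count is as close
#' as possible to `fraction` of the input.  The representative within each
#' voxel is chosen by a seeded draw, so identical inputs and seed give
#' identical output.
#'
#' @param coords N x 3 matrix (or [point_set]).
#' @param fraction Target retained fraction (0, 1].
#' @param seed Integer seed.
#' @return Integer vector of retained row indices.
#' @export
voxel_downsample <- function(coords, fraction, seed = 1L) {
  X <- .as_coords(coords)
  n <- nrow(X)
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1 || n <= 1) return(seq_len(n))
  target <- max(1L, round(fraction * n))
  rng <- apply(X, 2, range)
  count_at <- function(h) {
    key <- paste(floor((X[, 1] - rng[1, 1]) / h),
                 floor((X[, 2] - rng[1, 2]) / h),
                 floor((X[, 3] - rng[1, 3]) / h))
    length(unique(key))
  }
  ## bracket the pitch, then bisect on the (monotone) occupied-voxel count
  h_lo <- 1e-6 * max(rng[2, ] - rng[1, ] + 1)
  h_hi <- max(rng[2, ] - rng[1, ]) + 1
  for (it in 1:60) {
    h <- sqrt(h_lo * h_hi)
    cnt <- count_at(h)
    if (cnt > target) h_lo <- h else h_hi <- h
    if (abs(cnt - target) <= max(1, 0.02 * target)) break
  }
  key <- paste(floor((X[, 1] - rng[1, 1]) / h),
               floor((X[, 2] - rng[1, 2]) / h),
               floor((X[, 3] - rng[1, 3]) / h))
  groups <- split(seq_len(n), key)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed(sort(vapply(groups, function(g)
    if (length(g) == 1L) g else g[sample.int(length(g), 1L)], integer(1))))
}

#' Shape-preserving coarse-graining of a point set
#'
#' Peels the structure layer by layer: build the alpha shape, take its
#' boundary nodes, keep a decimated subset of them ([reduce_surface()]),
#' remove the whole boundary layer, and recurse on the interior; any
#' interior points remaining after the final layer are voxel-downsampled to
#' the same fraction.  Every returned point is one of the input points, so
#' the coarse model keeps the original coordinates as nodes.
#'
#' @param points A [point_set].
#' @param spec A [coarsen_spec()].
#' @return A [point_set] containing the retained subset; the retained
#'   indices are in attribute `kept_indices`.
#' @export
coarsen_structure <- function(points, spec) {
  stopifnot(inherits(points, "point_set"), inherits(spec, "coarsen_spec"))
  n <- nrow(points$coords)
  if (spec$fraction == 1) {
    out <- points
    attr(out, "kept_indices") <- seq_len(n)
    return(out)
  }
  work <- seq_len(n)
  kept <- integer(0)
  layer <- 0L
  while (layer < spec$n_layers && length(work) >= 4L) {
    mesh <- tryCatch(
      build_alpha_shape(points$coords[work, , drop = FALSE],
                        alpha = spec$alpha),
      error = function(e) NULL)
    if (is.null(mesh)) break
    surf <- boundary_surface(mesh)
    ## inner layers eventually become too small for edge collapse; fall
    ## back to the deterministic voxel downsampler for those
    keep_local <- tryCatch(
      as.integer(reduce_surface(surf, spec$fraction)),
      error = function(e)
        surf$surface_nodes[voxel_downsample(
          mesh$nodes[surf$surface_nodes, , drop = FALSE],
          spec$fraction, seed = spec$seed)])
    kept <- c(kept, work[keep_local])
    work <- work[-surf$surface_nodes]
    layer <- layer + 1L
  }
  if (length(work)) {
    ds <- voxel_downsample(points$coords[work, , drop = FALSE],
                           spec$fraction, seed = spec$seed)
    kept <- c(kept, work[ds])
  }
  kept <- sort(unique(kept))
  out <- subset_points(points, kept)
  attr(out, "kept_indices") <- kept
  out
}
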