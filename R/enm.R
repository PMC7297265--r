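## Anisotropic network model (ANM) baseline for solid-vs-network comparisons.

#' ANM parameters
#'
#' @param cutoff Contact cutoff distance in Angstrom (default 13, the
#'   conventional value for C-alpha ANM).
#' @param gamma Spring constant, kcal mol^-1 A^-2 (default 1; calibrate with
#'   [calibrate_gamma()]).
#' @return An `anm_params` object.
#' @export
anm_params <- function(cutoff = 13, gamma = 1) {
  stopifnot(cutoff > 0, gamma > 0)
  structure(list(cutoff = cutoff, gamma = gamma), class = "anm_params")
}

#' ANM Hessian matrix
#'
#' Standard anisotropic-network Hessian: for each pair (i, j) within the
#' cutoff, the off-diagonal 3 x 3 block is `-gamma r r' / |r|^2` and the
#' diagonal blocks are minus the row sums.  Symmetric positive
#' semidefinite with (at least) six zero modes; isolated nodes trigger a
#' warning since each adds three more zero modes.
#'
#' @param points A [point_set] or N x 3 matrix.
#' @param params [anm_params()].
#' @return Sparse symmetric 3N x 3N Hessian (kcal mol^-1 A^-2).
#' @export
anm_hessian <- function(points, params = anm_params()) {
  coords <- .as_coords(points)
  n <- nrow(coords)
  if (n < 2) stop("need at least two points")
  pairs <- .contact_pairs(coords, params$cutoff)
  if (!nrow(pairs)) stop("no contacts within the cutoff")
  deg <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s) without contacts: ",
            "expect extra zero modes")
  rij <- coords[pairs[, 2], , drop = FALSE] - coords[pairs[, 1], , drop = FALSE]
  r2 <- rowSums(rij^2)
  np <- nrow(pairs)
  ## 3x3 blocks, four per pair (ij, ji, ii, jj)
  bi <- rep(1:3, times = 3); bj <- rep(1:3, each = 3)
  blocks <- params$gamma * rij[, bi] * rij[, bj] / r2   # np x 9
  ii <- jj <- integer(36L * np); xx <- numeric(36L * np)
  base_i <- 3L * (pairs[, 1] - 1L); base_j <- 3L * (pairs[, 2] - 1L)
  slot <- function(k) (k - 1L) * 9L * np + seq_len(9L * np)
  ri <- rep(bi, each = np); rj <- rep(bj, each = np)
  bx <- as.vector(blocks)
  ii[slot(1)] <- rep(base_i, 9L) + ri; jj[slot(1)] <- rep(base_j, 9L) + rj
  xx[slot(1)] <- -bx
  ii[slot(2)] <- rep(base_j, 9L) + ri; jj[slot(2)] <- rep(base_i, 9L) + rj
  xx[slot(2)] <- -bx
  ii[slot(3)] <- rep(base_i, 9L) + ri; jj[slot(3)] <- rep(base_i, 9L) + rj
  xx[slot(3)] <- bx
  ii[slot(4)] <- rep(base_j, 9L) + ri; jj[slot(4)] <- rep(base_j, 9L) + rj
  xx[slot(4)] <- bx
  H <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * n, 3L * n))
  Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
}

## contact pairs within cutoff; grid (cell-list) binning keeps the candidate
## set near-linear in N instead of forming the full N^2 distance matrix
.contact_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n <= 1500L) {
    d <- as.matrix(stats::dist(coords))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    return(idx)
  }
  cell <- floor(sweep(coords, 2, apply(coords, 2, min)) / cutoff) + 1L
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  out_i <- list(); out_j <- list(); nb <- 0L
  cells <- split(seq_len(n), key)
  coord_key <- unique(cell)
  lookup <- cells
  for (ck in names(cells)) {
    c0 <- as.integer(strsplit(ck, " ")[[1]])
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      nk <- paste(c0[1] + dx, c0[2] + dy, c0[3] + dz)
      if (!is.null(lookup[[nk]])) cand <- c(cand, lookup[[nk]])
    }
    for (i in cells[[ck]]) {
      js <- cand[cand > i]
      if (!length(js)) next
      dd <- sqrt(rowSums(sweep(coords[js, , drop = FALSE], 2,
                               coords[i, ])^2))
      hit <- js[dd <= cutoff]
      if (length(hit)) {
        nb <- nb + 1L
        out_i[[nb]] <- rep(i, length(hit)); out_j[[nb]] <- hit
      }
    }
  }
  cbind(unlist(out_i), unlist(out_j))
}

#' ANM as a global system (Hessian + lumped masses)
#'
#' Packages the ANM Hessian with a diagonal lumped mass matrix (per-node
#' point masses, in contrast to the finite-element consistent mass) so that
#' [solve_modes()], [overlap()] and the spectrum utilities apply unchanged.
#'
#' @param points A [point_set] (masses are taken from it) or N x 3 matrix.
#' @param params [anm_params()].
#' @param unit_masses Use unit masses instead of the point masses?
#' @return A `global_system`.
#' @export
anm_system <- function(points, params = anm_params(), unit_masses = FALSE) {
  coords <- .as_coords(points)
  n <- nrow(coords)
  masses <- if (unit_masses || !inherits(points, "point_set"))
    rep(1, n) else points$masses
  H <- anm_hessian(coords, params)
  Ms <- Matrix::Diagonal(n, masses)
  structure(list(K = H, M = Matrix::Diagonal(3L * n, rep(masses, each = 3L)),
                 Ms = Ms, n_nodes = n,
                 params = structure(list(E = params$gamma, nu = NA,
                                         rho = NULL), class = "elastic_params"),
                 rho = NULL, masses = masses, mesh = NULL,
                 mass_type = "lumped"),
            class = "global_system")
}

#' ANM mean square fluctuations
#'
#' `msf_i = (kB T / gamma) trace([H^+]_ii)` with the six rigid-body modes
#' deflated, computed from the modal expansion of the Hessian built at unit
#' spring constant.  B-factors are `8 pi^2 / 3 * msf`.
#'
#' @param hessian Sparse ANM Hessian from [anm_hessian()] built at
#'   `gamma = 1`, or a `global_system` from [anm_system()].
#' @param gamma Spring constant scale (kcal mol^-1 A^-2).
#' @param T_K Temperature (K).
#' @param rigid_tol Relative zero-mode tolerance, default 1e-8.
#' @return A `fluct_profile` data frame (`msf`, `bfactor`).
#' @export
anm_msf <- function(hessian, gamma = 1, T_K = 298, rigid_tol = 1e-8) {
  H <- if (inherits(hessian, "global_system")) hessian$K else hessian
  Hd <- as.matrix(H)
  e <- eigen((Hd + t(Hd)) / 2, symmetric = TRUE)
  lam <- rev(e$values); V <- e$vectors[, rev(seq_len(ncol(Hd))), drop = FALSE]
  nz <- lam >= rigid_tol * max(lam)
  n_rigid <- sum(!nz)
  if (n_rigid > 6)
    warning("more than 6 near-zero modes (", n_rigid,
            "): the network is disconnected")
  contrib <- V[, nz, drop = FALSE]^2 %*% (1 / lam[nz])
  n <- nrow(Hd) / 3L
  msf <- .kB_kcalmol * T_K / gamma *
    colSums(matrix(contrib, nrow = 3L, ncol = n))
  out <- data.frame(msf = msf, bfactor = 8 * pi^2 / 3 * msf)
  class(out) <- c("fluct_profile", "data.frame")
  out
}

#' Calibrate the ANM spring constant against experimental B-factors
#'
#' Same least-squares scale as [calibrate_young_modulus()], applied to the
#' network model: predicted B-factors at unit gamma scale as `1/gamma`.
#'
#' @param msf_unit_gamma `fluct_profile` (or msf vector) computed at
#'   `gamma = 1`.
#' @param experimental_b Experimental B-factors (A^2).
#' @return List with `gamma` (kcal mol^-1 A^-2) and `pearson`.
#' @export
calibrate_gamma <- function(msf_unit_gamma, experimental_b) {
  fit <- calibrate_young_modulus(msf_unit_gamma, experimental_b)
  list(gamma = fit$E, pearson = fit$pearson,
       predicted_b = fit$predicted_b)
}
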