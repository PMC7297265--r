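## Normal modes of the (K, M) pencil, spectra, fluctuations, calibration.

#' Solve the generalized eigenproblem K v = lambda M v
#'
#' Computes the lowest eigenpairs of the assembled system.  For small
#' systems a dense symmetric decomposition (through the Cholesky factor of
#' `M`) is used; above `dense_limit` degrees of freedom a shift-invert
#' Krylov iteration on the sparse matrices computes only the requested
#' modes.  Eigenvectors are M-orthonormal (`v' M v = 1`); eigenvalues are
#' ascending; numerically-zero leading eigenvalues are flagged as rigid-body
#' modes (six for a free connected solid, six per component otherwise).
#'
#' @param system A `global_system` from [assemble()] (or [anm_system()]).
#' @param n_modes Number of lowest modes to return; NULL (default) returns
#'   all modes for dense solves and 50 for sparse ones.
#' @param dense_limit DOF count up to which the dense path is used
#'   (default 1800).
#' @param rigid_tol Relative tolerance for flagging rigid modes: eigenvalues
#'   below `rigid_tol * max(lambda)` count as zero.  Default 1e-8.
#' @return A `mode_set`: `values` (ascending), `vectors` (3N x k,
#'   M-orthonormal), `mass_weighted` (`M^(1/2) v`, unit Euclidean norm),
#'   `wavenumbers` (cm^-1), `n_rigid`, `n_nodes`.
#' @export
solve_modes <- function(system, n_modes = NULL, dense_limit = 1800,
                        rigid_tol = 1e-8) {
  stopifnot(inherits(system, "global_system"))
  n <- 3L * system$n_nodes
  if (!is.null(n_modes) && n_modes > n)
    stop("n_modes exceeds the number of degrees of freedom")
  dense <- n <= dense_limit || (!is.null(n_modes) && n_modes > n %/% 3L)
  if (dense) {
    K <- as.matrix(system$K); M <- as.matrix(system$M)
    R <- chol((M + t(M)) / 2)
    ## A = R^-T K R^-1, symmetric
    A <- backsolve(R, t(backsolve(R, t(K), transpose = TRUE)),
                   transpose = TRUE)
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    k <- if (is.null(n_modes)) n else n_modes
    sel <- n:(n - k + 1L)            # eigen() sorts descending
    vals <- e$values[sel]
    vecs <- backsolve(R, e$vectors[, sel, drop = FALSE])
  } else {
    k <- if (is.null(n_modes)) 50L else n_modes
    K <- system$K; M <- system$M
    sigma <- 1e-4 * (sum(Matrix::diag(K)) / sum(Matrix::diag(M)))
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(K + sigma * M),
                           LDL = FALSE)
    op <- function(x, args) as.numeric(Matrix::solve(ch, M %*% x))
    es <- RSpectra::eigs(op, k = k, which = "LM", n = n,
                         opts = list(retvec = TRUE))
    if (length(es$values) < k)
      stop("eigensolver did not converge; retry with a larger subspace ",
         "(higher n_modes) or the dense path")
    theta <- Re(es$values)
    vals <- 1 / theta - sigma
    ord <- order(vals)
    vals <- vals[ord]
    vecs <- Re(es$vectors[, ord, drop = FALSE])
    ## M-orthonormalize (modified Gram-Schmidt in the M inner product)
    for (j in seq_len(ncol(vecs))) {
      v <- vecs[, j]
      if (j > 1L) {
        prev <- vecs[, 1:(j - 1L), drop = FALSE]
        v <- v - prev %*% crossprod(prev, as.numeric(M %*% v))
      }
      vecs[, j] <- v / sqrt(as.numeric(crossprod(v, as.numeric(M %*% v))))
    }
  }
  vals[abs(vals) < .Machine$double.eps * max(abs(vals))] <- 0
  ## M-normalize (dense path)
  if (dense) {
    nrm <- sqrt(colSums(vecs * as.matrix(system$M %*% vecs)))
    vecs <- sweep(vecs, 2L, nrm, "/")
  }
  n_rigid <- sum(vals < rigid_tol * max(vals, na.rm = TRUE))
  vals <- pmax(vals, 0)
  q <- .mass_weight_modes(system, vecs)
  structure(list(values = vals, vectors = vecs, mass_weighted = q,
                 wavenumbers = to_wavenumbers(vals), n_rigid = n_rigid,
                 n_nodes = system$n_nodes, system = system),
            class = "mode_set")
}

## q_k = M^(1/2) v_k using the scalar-block structure M = Ms (x) I3.
.mass_weight_modes <- function(system, vecs) {
  n <- system$n_nodes
  Ms <- system$Ms
  if (isTRUE(Matrix::isDiagonal(Ms))) {
    s <- sqrt(Matrix::diag(Ms))
    return(vecs * rep(s, each = 3L))
  }
  if (n > 4000L) return(NULL)  # dense square root too large to be useful
  e <- eigen(as.matrix(Ms), symmetric = TRUE)
  S <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  out <- vecs
  for (c_ in 1:3) {
    rows <- seq(c_, 3L * n, by = 3L)
    out[rows, ] <- S %*% vecs[rows, , drop = FALSE]
  }
  out
}

#' @export
print.mode_set <- function(x, ...) {
  nz <- x$wavenumbers[(x$n_rigid + 1):min(length(x$values), x$n_rigid + 3)]
  cat(sprintf(
    "mode_set: %d modes (%d rigid), first wavenumbers: %s cm^-1\n",
    length(x$values), x$n_rigid,
    paste(sprintf("%.3g", nz), collapse = ", ")))
  invisible(x)
}

#' Eigenvalues to vibrational wavenumbers
#'
#' Converts eigenvalues of the (K, M) pencil (working units
#' kcal mol^-1 amu^-1 A^-2) to wavenumbers in cm^-1 via
#' `omega = sqrt(lambda_SI) / (2 pi c)`; the net conversion factor is about
#' 108.59 per sqrt(working-unit eigenvalue) and is derived from SI constants
#' at load time.
#'
#' @param eigvals Numeric vector of eigenvalues (>= 0 up to round-off).
#' @return Wavenumbers in cm^-1.
#' @export
to_wavenumbers <- function(eigvals) {
  if (any(eigvals < -1e-6 * max(abs(eigvals), 1)))
    stop("negative eigenvalue beyond tolerance; the system is not ",
         "positive semidefinite")
  .wavenumber_factor * sqrt(pmax(eigvals, 0))
}

#' Vibrational spectrum and power-law fit
#'
#' Histograms the non-rigid wavenumbers and fits `G(omega)`, the fraction of
#' modes below `omega`, with a power law `G ~ omega^p` by ordinary least
#' squares in log-log space.  The fit window is the lower half of the
#' spectrum (modes with `omega` at most the median), where the power-law
#' behaviour of globular-protein spectra is expected.
#'
#' @param modeset A `mode_set`, or a numeric vector of wavenumbers.
#' @param n_bins Histogram bins, default 30.
#' @return List with `exponent`, the fitted `prefactor`, a data frame
#'   `cumulative` (omega, G), and `histogram` (a [graphics::hist] object,
#'   not plotted).
#' @export
spectrum_and_powerfit <- function(modeset, n_bins = 30) {
  w <- if (inherits(modeset, "mode_set"))
    modeset$wavenumbers[-seq_len(modeset$n_rigid)] else as.numeric(modeset)
  w <- sort(w[w > 0])
  if (length(w) < 20) stop("need at least 20 non-rigid modes for a spectrum")
  G <- seq_along(w) / length(w)
  win <- w <= stats::median(w)
  fit <- stats::lm(log(G[win]) ~ log(w[win]))
  h <- graphics::hist(w, breaks = n_bins, plot = FALSE)
  list(exponent = unname(stats::coef(fit)[2]),
       prefactor = exp(unname(stats::coef(fit)[1])),
       cumulative = data.frame(omega = w, G = G),
       histogram = h)
}

#' Mean square fluctuations and predicted B-factors
#'
#' Thermal mean-square fluctuation of each node from the modal expansion
#' `msf_i = (kB T / E) * sum_k |v_k,i|^2 / lambda_k` over non-rigid modes,
#' where `v_k,i` is the 3-vector block of the M-orthonormal mode.  This
#' equals the i-th diagonal-block trace of the rigid-mode-deflated inverse
#' of the mass-weighted stiffness matrix.  Predicted B-factors are
#' `8 pi^2 / 3 * msf`.
#'
#' The modes are expected to come from an assembly at unit Young's modulus;
#' `E` then enters only as the external scale of the stiffness (msf is
#' proportional to `T/E`).
#'
#' @param modeset A `mode_set`.
#' @param E Young's modulus scale (kcal mol^-1 A^-3), > 0.
#' @param T_K Temperature in Kelvin (default 298).
#' @param experimental_b Optional vector of experimental B-factors; when
#'   given, the Pearson correlation with the prediction is reported.
#' @return A `fluct_profile` data frame with columns `msf` (A^2) and
#'   `bfactor` (A^2), plus attribute `pearson` when experimental values
#'   were supplied.
#' @export
mean_square_fluctuations <- function(modeset, E = 1, T_K = 298,
                                     experimental_b = NULL) {
  stopifnot(inherits(modeset, "mode_set"))
  if (E <= 0) stop("E must be positive")
  if (T_K <= 0) stop("temperature must be positive")
  idx <- seq_along(modeset$values) > modeset$n_rigid
  v <- modeset$vectors[, idx, drop = FALSE]
  lam <- modeset$values[idx]
  n <- modeset$n_nodes
  contrib <- v^2 %*% (1 / lam)           # 3N x 1
  msf <- .kB_kcalmol * T_K / E *
    colSums(matrix(contrib, nrow = 3L, ncol = n))
  out <- data.frame(msf = msf, bfactor = 8 * pi^2 / 3 * msf)
  class(out) <- c("fluct_profile", "data.frame")
  if (!is.null(experimental_b))
    attr(out, "pearson") <- stats::cor(out$bfactor, experimental_b)
  out
}

#' Calibrate Young's modulus against experimental B-factors
#'
#' Predicted B-factors scale as `1/E`; the least-squares scale that best
#' matches experiment is `E = sum(P^2) / sum(P B_exp)` where `P` is the
#' prediction at unit modulus.  Reports the fitted modulus (working units
#' and GPa) and the Pearson correlation between prediction and experiment
#' (which is scale-free).
#'
#' @param msf_unit_E A `fluct_profile` computed at `E = 1` (see
#'   [mean_square_fluctuations()]), or a numeric msf vector.
#' @param experimental_b Experimental B-factors (A^2), one per node.
#' @return List with `E` (kcal mol^-1 A^-3), `E_GPa`, `pearson` and the
#'   rescaled `predicted_b`.
#' @export
calibrate_young_modulus <- function(msf_unit_E, experimental_b) {
  msf <- if (inherits(msf_unit_E, "fluct_profile")) msf_unit_E$msf
         else as.numeric(msf_unit_E)
  b <- as.numeric(experimental_b)
  if (length(b) != length(msf))
    stop("experimental B-factors must match the number of nodes")
  if (stats::sd(b) == 0) stop("experimental B-factor column has no variance")
  pred1 <- 8 * pi^2 / 3 * msf            # prediction at E = 1
  E <- sum(pred1^2) / sum(pred1 * b)
  list(E = E, E_GPa = E * .kcalmolA3_GPa,
       pearson = stats::cor(pred1, b),
       predicted_b = pred1 / E)
}

#' Axial-mode wavenumber of a bar-shaped solid
#'
#' Identifies the fundamental axial (half-wave compression) mode of a
#' bar-like system by projecting the modes onto the pattern
#' `u_x = cos(pi x / L)` and reports both the wavenumber of the
#' best-overlapping mode and the projection-weighted modal average
#' (the Rayleigh quotient of the interpolated pattern, which is the robust
#' estimator when the axial branch hybridizes with nearly degenerate
#' bending modes).  The continuum reference is
#' `omega = (1/2L) sqrt(E/rho)` expressed in cm^-1.
#'
#' @param system The assembled `global_system` (its mesh supplies the node
#'   coordinates).
#' @param modeset A `mode_set` from [solve_modes()] on that system.
#' @param axis Bar axis: `"x"`, `"y"` or `"z"`.
#' @return List with `wavenumber` (best mode), `wavenumber_rayleigh`,
#'   `mode` (index among all computed modes), `purity` (squared overlap of
#'   the pattern with the best mode) and `continuum` (closed-form cm^-1).
#' @export
axial_wavenumber <- function(system, modeset, axis = c("x", "y", "z")) {
  stopifnot(inherits(system, "global_system"), inherits(modeset, "mode_set"))
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  coords <- system$mesh$nodes
  xs <- coords[, ai]
  L <- diff(range(xs))
  p <- numeric(3L * system$n_nodes)
  p[seq(ai, length(p), by = 3L)] <- cos(pi * (xs - min(xs)) / L)
  Mp <- as.numeric(system$M %*% p)
  O2 <- as.numeric(crossprod(modeset$vectors, Mp))^2 / sum(p * Mp)
  k <- which.max(O2)
  lam_ray <- sum(p * as.numeric(system$K %*% p)) / sum(p * Mp)
  cont <- .wavenumber_factor * pi / L * sqrt(system$params$E / system$rho)
  list(wavenumber = modeset$wavenumbers[k],
       wavenumber_rayleigh = to_wavenumbers(lam_ray),
       mode = k, purity = O2[k], continuum = cont)
}
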