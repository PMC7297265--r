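## Overlap between conformational changes and normal modes.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Rotates and translates `mobile` onto `target`, minimizing the RMSD.
#' Overlaps between a conformational change and internal modes are
#' meaningless unless the rigid-body offset between the two conformations
#' is removed first.
#'
#' @param mobile,target N x 3 coordinate matrices (same node order).
#' @param weights Optional per-point weights (e.g. masses).
#' @return The superposed copy of `mobile`.
#' @export
superpose <- function(mobile, target, weights = NULL) {
  X <- .as_coords(mobile); Y <- .as_coords(target)
  if (!identical(dim(X), dim(Y))) stop("coordinate sets differ in size")
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(weights)
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  H <- crossprod(X0 * w, Y0)
  s <- svd(H)
  d <- sign(det(crossprod(t(s$v), t(s$u))))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(X0 %*% t(R), 2, cy, "+")
}

#' Displacement vector between two conformations
#'
#' Superposes the second conformation onto the first (unless
#' `superpose = FALSE`) and returns the per-node displacement.
#'
#' @param from,to [point_set]s or N x 3 matrices with identical node order.
#' @param superpose Remove the rigid-body offset first?  Default TRUE.
#' @return N x 3 displacement matrix (A).
#' @export
conformational_displacement <- function(from, to, superpose = TRUE) {
  A <- .as_coords(from); B <- .as_coords(to)
  if (!identical(dim(A), dim(B))) stop("conformations differ in node count")
  if (superpose) B <- superpose(B, A)
  B - A
}

#' Overlap of a displacement with the normal modes
#'
#' Projects a displacement `d` onto the mass-weighted modes
#' `q_k = M^(1/2) v_k`: `O_k = d . q_k / |d|`.  Because the `q_k` form a
#' complete orthonormal basis, `sum_k O_k^2 = 1` over all modes (Parseval).
#' Rigid modes are excluded from the report and mode indices count from the
#' first non-rigid mode as 1.
#'
#' Summary metrics: `alpha1..3`, the three largest `|O_k|`; `delta_m =
#' sqrt(sum_{k<=m} O_k^2)` for m = 3, 5, 10 (cumulative overlap over the
#' lowest m non-rigid modes); `n_alpha1`, the index of the best-overlapping
#' mode; and `n_sigma90`, the smallest m with `sum_{k<=m} O_k^2 >= 0.90`
#' (NA if the computed modes do not reach 90%).
#'
#' @param d Displacement: N x 3 matrix or 3N vector (node order of the
#'   system).
#' @param modeset A `mode_set` with mass-weighted modes available.
#' @return An `overlap_report`: data frame `per_mode` (mode, eigenvalue,
#'   wavenumber, overlap, cumulative) and the summary metrics.
#' @export
overlap <- function(d, modeset) {
  stopifnot(inherits(modeset, "mode_set"))
  d <- if (is.matrix(d)) as.vector(t(d)) else as.numeric(d)
  if (length(d) != 3L * modeset$n_nodes)
    stop("displacement length does not match the system's node count")
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("zero displacement vector")
  if (is.null(modeset$mass_weighted))
    stop("mass-weighted modes unavailable (system too large)")
  idx <- seq_along(modeset$values) > modeset$n_rigid
  q <- modeset$mass_weighted[, idx, drop = FALSE]
  ## mass-weight the displacement direction consistently with Eq (5)-(6):
  ## project the raw displacement on the orthonormal q basis
  O <- as.numeric(crossprod(q, d)) / nd
  cum <- cumsum(O^2)
  m <- length(O)
  per <- data.frame(mode = seq_len(m),
                    eigenvalue = modeset$values[idx],
                    wavenumber = modeset$wavenumbers[idx],
                    overlap = O, cumulative = cum)
  a_ord <- order(abs(O), decreasing = TRUE)
  n90 <- which(cum >= 0.90)
  structure(list(per_mode = per,
                 alpha1 = abs(O)[a_ord[1]],
                 alpha2 = if (m >= 2) abs(O)[a_ord[2]] else NA_real_,
                 alpha3 = if (m >= 3) abs(O)[a_ord[3]] else NA_real_,
                 delta3 = sqrt(cum[min(3, m)]),
                 delta5 = sqrt(cum[min(5, m)]),
                 delta10 = sqrt(cum[min(10, m)]),
                 n_alpha1 = a_ord[1],
                 n_sigma90 = if (length(n90)) n90[1] else NA_integer_),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    paste0("overlap_report: alpha1-3 = %.3f %.3f %.3f | delta(3,5,10) = ",
           "%.3f %.3f %.3f | N_alpha1 = %d | N_sigma90 = %s\n"),
    x$alpha1, x$alpha2, x$alpha3, x$delta3, x$delta5, x$delta10,
    x$n_alpha1, ifelse(is.na(x$n_sigma90), "NA", x$n_sigma90)))
  invisible(x)
}

#' Average overlap metrics over a benchmark of conformational pairs
#'
#' Means of the per-pair overlap summary metrics across a set of reports,
#' formatted as one row per model/direction as is conventional for
#' open-to-closed benchmark tables.
#'
#' @param reports List of `overlap_report` objects.
#' @param label Row label for the summary (default "ESM").
#' @return One-row data frame with means of alpha1..3, delta3/5/10,
#'   n_alpha1, n_sigma90 and the number of pairs.
#' @export
benchmark_metrics <- function(reports, label = "ESM") {
  if (inherits(reports, "overlap_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, TRUE, "overlap_report")))
  g <- function(f) mean(vapply(reports, function(r) as.numeric(r[[f]]),
                               numeric(1)), na.rm = TRUE)
  data.frame(model = label,
             alpha1 = g("alpha1"), alpha2 = g("alpha2"), alpha3 = g("alpha3"),
             delta3 = g("delta3"), delta5 = g("delta5"),
             delta10 = g("delta10"),
             n_alpha1 = g("n_alpha1"), n_sigma90 = g("n_sigma90"),
             n_pairs = length(reports))
}
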