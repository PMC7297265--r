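#' Labelled 3-D point set with masses
#'
#' The nodes of every model in the package: coordinates in Angstrom, one mass
#' per point (amu) and, when the points came from a crystal structure, the
#' experimental B-factor column (A^2).
#'
#' @param coords Numeric N x 3 matrix of coordinates (A).
#' @param masses Numeric vector of per-point masses (amu); recycled if of
#'   length 1.  Default 110 amu, a typical average residue mass.
#' @param labels Character vector of per-point source tags (chain/residue or
#'   voxel index).  Defaults to `"p1" ... "pN"`.
#' @param bfactors Optional numeric vector of experimental B-factors (A^2).
#' @param dedup Drop exactly coinciding points (keeping the first)?  Default
#'   TRUE.
#'
#' @return An object of class `point_set` with fields `coords`, `masses`,
#'   `labels`, `bfactors`.
#' @export
point_set <- function(coords, masses = 110, labels = NULL, bfactors = NULL,
                      dedup = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (ncol(coords) != 3L) stop("`coords` must have three columns")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  masses <- rep_len(as.numeric(masses), n)
  if (any(masses <= 0)) stop("masses must be positive")
  if (is.null(labels)) labels <- paste0("p", seq_len(n))
  labels <- rep_len(as.character(labels), n)
  if (!is.null(bfactors)) bfactors <- rep_len(as.numeric(bfactors), n)
  if (dedup && n > 1L) {
    key <- paste(coords[, 1], coords[, 2], coords[, 3])
    keep <- !duplicated(key)
    if (!all(keep)) {
      coords <- coords[keep, , drop = FALSE]
      masses <- masses[keep]
      labels <- labels[keep]
      if (!is.null(bfactors)) bfactors <- bfactors[keep]
    }
  }
  structure(list(coords = coords, masses = masses, labels = labels,
                 bfactors = bfactors),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set: %d points, total mass %.1f amu%s\n",
              nrow(x$coords), sum(x$masses),
              if (is.null(x$bfactors)) "" else ", with B-factors"))
  invisible(x)
}

#' @export
as.data.frame.point_set <- function(x, ...) {
  d <- data.frame(label = x$labels, x = x$coords[, 1], y = x$coords[, 2],
                  z = x$coords[, 3], mass = x$masses)
  if (!is.null(x$bfactors)) d$bfactor <- x$bfactors
  d
}

#' @export
length.point_set <- function(x) nrow(x$coords)

## Coerce point_set-or-matrix arguments to a coordinate matrix.
.as_coords <- function(x) {
  if (inherits(x, "point_set")) return(x$coords)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L) stop("expected a point_set or an N x 3 matrix")
  m
}

## Subset a point_set by index, preserving all fields.
subset_points <- function(ps, idx) {
  point_set(ps$coords[idx, , drop = FALSE], ps$masses[idx], ps$labels[idx],
            if (is.null(ps$bfactors)) NULL else ps$bfactors[idx],
            dedup = FALSE)
}
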