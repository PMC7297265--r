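#' Delaunay tetrahedralization of a 3-D point set
#'
#' Computes the full Delaunay tetrahedralization (all 3-simplices) of the
#' points.  The triangulation itself is delegated to Qhull through
#' `scipy.spatial.Delaunay` in a Python subprocess; cospherical ties are
#' resolved by Qhull's symbolic joggle/merge handling, so results can differ
#' between triangulation backends only in zero-measure cases.
#'
#' @param points A [point_set] or N x 3 coordinate matrix, N >= 4.
#' @return Integer T x 4 matrix of 1-based node indices.
#' @export
delaunay_tetrahedra <- function(points) {
  coords <- .as_coords(points)
  if (nrow(coords) < 4L) stop("need at least 4 points for a tetrahedralization")
  py <- .find_python()
  fin <- tempfile("aesm-dt-", fileext = ".bin")
  fout <- tempfile("aesm-dt-", fileext = ".bin")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeBin(as.numeric(t(coords)), fin, size = 8)
  script <- system.file("python", "delaunay3d.py", package = "aesm",
                        mustWork = TRUE)
  res <- suppressWarnings(
    system2(py, shQuote(c(script, fin, fout)), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status == 3L)
    stop("degenerate input: points do not span three dimensions")
  if (!is.null(status) && status != 0L)
    stop("Delaunay backend failed: ", paste(res, collapse = "\n"))
  con <- file(fout, "rb")
  on.exit(close(con), add = TRUE, after = FALSE)
  nt <- readBin(con, "integer", n = 1L, size = 4L)
  idx <- readBin(con, "integer", n = 4L * nt, size = 4L)
  matrix(idx, ncol = 4L, byrow = TRUE) + 1L
}

.find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no `python` interpreter with scipy found on the PATH ",
       "(required for Delaunay tetrahedralization)")
}
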