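## Tetrahedral mesh export for finite-element programs, plus minimal
## readers used for round-trip validation.

#' Export a tetrahedral mesh for finite-element analysis
#'
#' Writes the solid as 4-node tetrahedral elements in legacy VTK
#' unstructured-grid, Abaqus INP (C3D4 elements) or GMSH MSH v2.2 format,
#' with 1-based node numbering in INP/MSH, so the alpha-shape mesh can be
#' fed directly into a finite-element program.
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file.
#' @param format `"vtk"`, `"inp"` or `"msh"`.
#' @return Invisibly, `path`.
#' @export
export_mesh <- function(mesh, path, format = c("vtk", "inp", "msh")) {
  stopifnot(inherits(mesh, "tet_mesh"))
  format <- match.arg(format)
  nodes <- mesh$nodes; tets <- mesh$tets
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(nodes); nt <- nrow(tets)
  if (format == "vtk") {
    writeLines(c("# vtk DataFile Version 2.0",
                 "tetrahedral solid", "ASCII",
                 "DATASET UNSTRUCTURED_GRID",
                 sprintf("POINTS %d double", n)), con)
    writeLines(sprintf("%.8g %.8g %.8g", nodes[, 1], nodes[, 2],
                       nodes[, 3]), con)
    writeLines(sprintf("CELLS %d %d", nt, 5L * nt), con)
    writeLines(sprintf("4 %d %d %d %d", tets[, 1] - 1L, tets[, 2] - 1L,
                       tets[, 3] - 1L, tets[, 4] - 1L), con)
    writeLines(sprintf("CELL_TYPES %d", nt), con)
    writeLines(rep("10", nt), con)            # VTK_TETRA
  } else if (format == "inp") {
    writeLines("*HEADING", con)
    writeLines("alpha-shape tetrahedral solid", con)
    writeLines("*NODE", con)
    writeLines(sprintf("%d, %.8g, %.8g, %.8g", seq_len(n), nodes[, 1],
                       nodes[, 2], nodes[, 3]), con)
    writeLines("*ELEMENT, TYPE=C3D4", con)
    writeLines(sprintf("%d, %d, %d, %d, %d", seq_len(nt), tets[, 1],
                       tets[, 2], tets[, 3], tets[, 4]), con)
  } else {
    writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
                 "$Nodes", as.character(n)), con)
    writeLines(sprintf("%d %.8g %.8g %.8g", seq_len(n), nodes[, 1],
                       nodes[, 2], nodes[, 3]), con)
    writeLines(c("$EndNodes", "$Elements", as.character(nt)), con)
    ## element type 4 = 4-node tetrahedron, 2 tags (physical, geometric)
    writeLines(sprintf("%d 4 2 0 0 %d %d %d %d", seq_len(nt), tets[, 1],
                       tets[, 2], tets[, 3], tets[, 4]), con)
    writeLines("$EndElements", con)
  }
  invisible(path)
}

#' Read back a tetrahedral mesh written by [export_mesh()]
#'
#' Minimal readers for the three export formats, returning nodes and
#' 1-based tetrahedron indices; intended for round-trip validation and for
#' re-importing externally modified meshes.
#'
#' @param path Mesh file.
#' @param format `"vtk"`, `"inp"` or `"msh"`.
#' @return List with `nodes` (N x 3) and `tets` (T x 4, 1-based).
#' @export
read_mesh <- function(path, format = c("vtk", "inp", "msh")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  num <- function(x) as.numeric(strsplit(trimws(x), "[ ,]+")[[1]])
  if (format == "vtk") {
    ip <- grep("^POINTS", lines)
    n <- as.integer(strsplit(lines[ip], " +")[[1]][2])
    nodes <- do.call(rbind, lapply(lines[(ip + 1):(ip + n)], num))
    ic <- grep("^CELLS", lines)
    nt <- as.integer(strsplit(lines[ic], " +")[[1]][2])
    cells <- do.call(rbind, lapply(lines[(ic + 1):(ic + nt)], num))
    list(nodes = nodes, tets = cells[, 2:5, drop = FALSE] + 1L)
  } else if (format == "inp") {
    istart <- grep("^\\*NODE", lines, ignore.case = TRUE)[1] + 1L
    iend <- grep("^\\*ELEMENT", lines, ignore.case = TRUE)[1]
    nodes <- do.call(rbind, lapply(lines[istart:(iend - 1)], num))
    body <- lines[(iend + 1):length(lines)]
    body <- body[!grepl("^\\*", body) & nzchar(trimws(body))]
    el <- do.call(rbind, lapply(body, num))
    list(nodes = nodes[order(nodes[, 1]), 2:4, drop = FALSE],
         tets = el[, 2:5, drop = FALSE])
  } else {
    in0 <- grep("^\\$Nodes", lines) + 1L
    n <- as.integer(lines[in0])
    nodes <- do.call(rbind, lapply(lines[(in0 + 1):(in0 + n)], num))
    ie0 <- grep("^\\$Elements", lines) + 1L
    nt <- as.integer(lines[ie0])
    el <- do.call(rbind, lapply(lines[(ie0 + 1):(ie0 + nt)], num))
    ntags <- el[1, 3]
    list(nodes = nodes[order(nodes[, 1]), 2:4, drop = FALSE],
         tets = el[, (4 + ntags):(7 + ntags), drop = FALSE])
  }
}
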