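## Reading atomic structures into point sets.

## Average residue masses (amu) for the 20 standard amino acids (residue in
## chain context, i.e. amino acid minus water); fallback 110 for others.
.residue_mass <- c(
  ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLN = 128.13, GLU = 129.12, GLY = 57.05, HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO = 97.12,
  SER = 87.08, THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13)

.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, SE = 78.971, FE = 55.845,
                   ZN = 65.38, MG = 24.305, CA = 40.078, MN = 54.938)

#' Read an atomic structure (PDB or mmCIF)
#'
#' Parses all atoms of the selected model, applying the alternate-location
#' policy, always excluding hydrogens, and recording any biological-assembly
#' operators (REMARK 350 BIOMT records) found in a PDB file.  Atom-record
#' parsing is delegated to bio3d; assembly operators are read from the file
#' text directly.
#'
#' @param path Path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param model_index Model to read from multi-model files (default 1).
#' @param altloc_policy `"highest-occupancy"` (default: per altloc group keep
#'   the highest occupancy, ties broken alphabetically) or `"first"`.
#' @return A `structure3d` object: `atoms` data frame (chain, resno, resid,
#'   elety, elesy, x, y, z, o, b) and `transforms`, a list of
#'   `list(R = 3x3, t = length-3)` operators.
#' @export
read_structure <- function(path, model_index = 1,
                           altloc_policy = c("highest-occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE),
    error = function(e) stop("unparsable structure file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("empty model: no ATOM records in ", path)
  ## model selection for multi-model files
  if (model_index > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model_index)
      stop("model ", model_index, " not present (file has ",
           max(1, nrow(pdb$xyz)), ")")
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at[, c("x", "y", "z")] <- xyz[as.integer(rownames(at)), ]
  }
  ## drop hydrogens
  h <- !is.na(at$elesy) & toupper(at$elesy) == "H"
  h <- h | grepl("^[0-9]*H", at$elety)
  at <- at[!h, , drop = FALSE]
  ## altloc policy
  alt <- at$alt
  if (any(!is.na(alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    o <- if (altloc_policy == "highest-occupancy")
      order(key, -replace(at$o, is.na(at$o), 0),
            replace(alt, is.na(alt), "")) else order(key, seq_len(nrow(at)))
    at <- at[o, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
             drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  transforms <- if (!is_cif) .read_biomt(path) else list()
  structure(list(atoms = at, transforms = transforms, source = path),
            class = "structure3d")
}

## REMARK 350 BIOMT parsing; returns list of list(R, t)
.read_biomt <- function(path) {
  lines <- grep("^REMARK 350 +BIOMT[123]", readLines(path, warn = FALSE),
                value = TRUE)
  if (!length(lines)) return(list())
  rows <- lapply(lines, function(l) {
    toks <- strsplit(trimws(substring(l, 12)), " +")[[1]]
    ## toks: BIOMTn  opid  r1 r2 r3 t
    c(as.numeric(substring(toks[1], 6)), as.numeric(toks[2]),
      as.numeric(toks[3:6]))
  })
  tab <- do.call(rbind, rows)
  ops <- split(as.data.frame(tab), tab[, 2])
  out <- lapply(ops, function(op) {
    op <- op[order(op[[1]]), ]
    R <- as.matrix(op[, 3:5])
    dimnames(R) <- NULL
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      warning("assembly operator rotation is not orthonormal")
    list(R = R, t = as.numeric(op[[6]]))
  })
  names(out) <- NULL
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d chain(s), %d assembly operator(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              length(x$transforms)))
  invisible(x)
}

#' Expand a structure by its biological-assembly operators
#'
#' Replicates all atoms under each recorded transform; chain identifiers are
#' suffixed with the operator number so copies remain distinguishable.  A
#' structure without transforms is returned unchanged with a warning.
#'
#' @param structure A `structure3d`.
#' @return A `structure3d` with `k * n` atoms for `k` operators.
#' @export
apply_assembly <- function(structure) {
  stopifnot(inherits(structure, "structure3d"))
  if (!length(structure$transforms)) {
    warning("structure has no assembly operators; returning it unchanged")
    return(structure)
  }
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  copies <- lapply(seq_along(structure$transforms), function(i) {
    op <- structure$transforms[[i]]
    at <- structure$atoms
    new_xyz <- xyz %*% t(op$R)
    at$x <- new_xyz[, 1] + op$t[1]
    at$y <- new_xyz[, 2] + op$t[2]
    at$z <- new_xyz[, 3] + op$t[3]
    at$chain <- paste0(at$chain, "_", i)
    at
  })
  structure(list(atoms = do.call(rbind, copies), transforms = list(),
                 source = structure$source),
            class = "structure3d")
}

#' Select model nodes from a structure
#'
#' Builds the [point_set] of model nodes.  C-alpha nodes carry their
#' residue's total mass (standard average residue masses); all-heavy-atom
#' nodes carry atomic masses.  Experimental B-factors are copied from the
#' selected atoms.  Residues can be excluded explicitly (e.g. disconnected
#' termini) with `exclude_residues`.
#'
#' @param structure A `structure3d`.
#' @param selector `"calpha"`, `"heavy"` (all heavy atoms), or
#'   `"every-kth-calpha"` with stride `k`.
#' @param k Stride for `"every-kth-calpha"` (keeps residues 1, 1+k, ... per
#'   chain).
#' @param exclude_residues Optional data frame with columns `chain`,
#'   `from`, `to` giving residue ranges to drop (chain NA = any chain).
#' @return A [point_set].
#' @export
select_nodes <- function(structure,
                         selector = c("calpha", "heavy",
                                      "every-kth-calpha"),
                         k = 1, exclude_residues = NULL) {
  stopifnot(inherits(structure, "structure3d"))
  selector <- match.arg(selector)
  at <- structure$atoms
  if (!is.null(exclude_residues)) {
    drop <- rep(FALSE, nrow(at))
    for (i in seq_len(nrow(exclude_residues))) {
      ex <- exclude_residues[i, ]
      hit <- at$resno >= ex$from & at$resno <= ex$to
      if (!is.na(ex$chain))
        hit <- hit & sub("_[0-9]+$", "", at$chain) == ex$chain
      drop <- drop | hit
    }
    at <- at[!drop, , drop = FALSE]
  }
  if (selector %in% c("calpha", "every-kth-calpha")) {
    at <- at[at$elety == "CA", , drop = FALSE]
    if (selector == "every-kth-calpha" && k > 1) {
      sel <- unlist(lapply(split(seq_len(nrow(at)), at$chain), function(idx)
        idx[seq(1, length(idx), by = k)]), use.names = FALSE)
      at <- at[sort(sel), , drop = FALSE]
    }
    masses <- unname(.residue_mass[at$resid])
    masses[is.na(masses)] <- 110
  } else {
    masses <- unname(.element_mass[toupper(at$elesy)])
    masses[is.na(masses)] <- 12.011
  }
  if (nrow(at) < 4)
    stop("selector yields only ", nrow(at),
         " node(s); at least 4 are needed")
  point_set(as.matrix(at[, c("x", "y", "z")]), masses = masses,
            labels = paste0(at$chain, ":", at$resno, ":", at$elety),
            bfactors = at$b)
}
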