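toy_pdb <- withr::local_tempfile(fileext = ".pdb")
write_toy_pdb(toy_pdb, n_res = 12)

test_that("PDB parsing preserves atoms, B-factors and assembly operators", {
  s <- read_structure(toy_pdb)
  ## 12 CA + N + C + O from residue 1; altloc group collapsed; H excluded
  expect_identical(nrow(s$atoms), 15L)
  expect_false(any(grepl("H", s$atoms$elety)))
  expect_length(s$transforms, 2L)
  expect_equal(s$transforms[[1]]$R, diag(3), tolerance = 1e-9)
  expect_equal(s$transforms[[2]]$t, c(30, 0, 0), tolerance = 1e-9)
  ## each operator's rotation is orthonormal
  for (op in s$transforms)
    expect_equal(crossprod(op$R), diag(3), tolerance = 1e-6)
  ## B column preserved (residue r has B = 20 + r in the fixture)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(ca$b, 20 + ca$resno, tolerance = 1e-9)
  expect_error(read_structure(tempfile()), "cannot read")
})

test_that("altloc policies keep one atom per group as specified", {
  ## fixture: residue-1 CA has altloc A (occ 0.4, x=1.0), B (occ 0.6, x=1.2)
  hi <- read_structure(toy_pdb, altloc_policy = "highest-occupancy")
  expect_equal(hi$atoms$x[hi$atoms$elety == "CA" & hi$atoms$resno == 1], 1.2)
  first <- read_structure(toy_pdb, altloc_policy = "first")
  expect_equal(first$atoms$x[first$atoms$elety == "CA" &
                               first$atoms$resno == 1], 1.0)
})

test_that("node selection carries masses, stride and exclusions", {
  s <- read_structure(toy_pdb)
  ca <- select_nodes(s, "calpha")
  expect_identical(nrow(ca$coords), 12L)
  expect_equal(ca$masses[1], 71.08)          # ALA residue mass
  expect_identical(ca$bfactors, 20 + (1:12))
  k3 <- select_nodes(s, "every-kth-calpha", k = 3)
  expect_identical(nrow(k3$coords), 4L)       # residues 1, 4, 7, 10
  expect_equal(k3$coords[, 1], c(1.2, 12, 21, 30), tolerance = 1e-9)
  heavy <- select_nodes(s, "heavy")
  expect_identical(nrow(heavy$coords), 15L)
  expect_equal(sort(unique(round(heavy$masses, 3))),
               c(12.011, 14.007, 15.999))
  ex <- select_nodes(s, "calpha",
                     exclude_residues = data.frame(chain = "A", from = 1,
                                                   to = 6))
  expect_identical(nrow(ex$coords), 6L)
  expect_error(select_nodes(s, "every-kth-calpha", k = 6), "at least 4")
})

test_that("assembly expansion replicates atoms under every operator", {
  s <- read_structure(toy_pdb)
  sa <- apply_assembly(s)
  expect_identical(nrow(sa$atoms), 2L * nrow(s$atoms))
  ## copy 2 is the 180-degree z-rotation plus (30, 0, 0)
  ca1 <- sa$atoms[sa$atoms$chain == "A_1" & sa$atoms$elety == "CA", ]
  ca2 <- sa$atoms[sa$atoms$chain == "A_2" & sa$atoms$elety == "CA", ]
  expect_equal(ca2$x, 30 - ca1$x, tolerance = 1e-6)
  expect_equal(ca2$y, -ca1$y, tolerance = 1e-6)
  expect_equal(ca2$z, ca1$z, tolerance = 1e-6)
  s0 <- s; s0$transforms <- list()
  expect_warning(unchanged <- apply_assembly(s0), "no assembly")
  expect_identical(nrow(unchanged$atoms), nrow(s$atoms))
})

test_that("hexamer-style residue accounting is exact on a synthetic chain", {
  ## synthetic stand-in for a capsid-protein chain: 216 solved residues,
  ## 6 disconnected N-terminal ones excluded, expanded by 6 operators
  f <- withr::local_tempfile(fileext = ".pdb")
  biomt <- unlist(lapply(1:6, function(k) {
    th <- 2 * pi * (k - 1) / 6
    sprintf(paste0("REMARK 350   BIOMT%d %3d %9.6f %9.6f %9.6f %14.5f"),
            1:3, k,
            c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1),
            c(40 * (k %% 2), 0, 0))
  }))
  set.seed(1)
  xyz <- cbind(cumsum(runif(216, 2, 3.8)), rnorm(216), rnorm(216))
  at <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    1:216, 1:216, xyz[, 1], xyz[, 2], xyz[, 3], 1, 30)
  writeLines(c(biomt, at, "END"), f)
  s <- read_structure(f)
  expect_identical(nrow(s$atoms), 216L)
  hexamer <- apply_assembly(s)
  nodes <- select_nodes(hexamer, "calpha",
                        exclude_residues = data.frame(chain = "A", from = 1,
                                                      to = 6))
  expect_identical(nrow(nodes$coords), 210L * 6L)   # 1260
})

test_that("density maps round-trip through MRC and scale with spacing", {
  g <- make_sphere_map(radius = 5, voxel = 1)
  f <- withr::local_tempfile(fileext = ".mrc")
  write_density(g, f)
  g2 <- read_density(f)
  expect_identical(dim(g2$values), dim(g$values))
  expect_equal(g2$values, g$values, tolerance = 1e-7)
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
  ## non-unit voxel spacing scales world coordinates linearly: same
  ## array, spacing 1.2 -> every coordinate multiplied by 1.2
  g1 <- make_sphere_map(radius = 6, voxel = 1)
  g12 <- density_grid(origin = g1$origin * 1.2, spacing = rep(1.2, 3),
                      values = g1$values)
  p1 <- points_from_density(g1, 0.5)
  p12 <- points_from_density(g12, 0.5)
  expect_equal(p12$coords, 1.2 * p1$coords, tolerance = 1e-9)
  expect_error(read_density(f <- {
    ff <- withr::local_tempfile(); writeBin(raw(100), ff); ff
  }), "bad MRC")
})

test_that("axis-permuted maps land on the same world coordinates", {
  g <- make_sphere_map(radius = 4, voxel = 1)
  ## write a twin with permuted axis order (z fastest): mapc/mapr/maps 3,2,1
  f <- withr::local_tempfile(fileext = ".mrc")
  d <- dim(g$values)
  con <- file(f, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(rev(d)); wi(2); wi(c(0, 0, 0)); wi(rev(d))
  wf(rev(d) * g$spacing); wf(c(90, 90, 90))
  wi(c(3, 2, 1))                                  # columns are z!
  wf(c(min(g$values), max(g$values), mean(g$values)))
  wi(rep(0, 2)); wi(rep(0, 25)); wf(g$origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wf(0); wi(0); writeBin(raw(800), con)
  wf(as.numeric(aperm(g$values, c(3, 2, 1))))
  close(con)
  gp <- read_density(f)
  expect_equal(gp$values, g$values, tolerance = 1e-7)
  expect_equal(gp$origin, g$origin, tolerance = 1e-6)
})

test_that("density thresholding counts voxels and shrinks monotonically", {
  g <- make_sphere_map(radius = 6, voxel = 1)
  pts <- points_from_density(g, 0.5)
  expect_equal(nrow(pts$coords), 4 / 3 * pi * 6^3, tolerance = 0.05)
  ## bounding box matches the sphere diameter within one voxel
  bb <- apply(pts$coords, 2, function(x) diff(range(x)))
  expect_true(all(abs(bb - 12) <= 1))
  ## monotone non-increasing count in the threshold
  counts <- vapply(c(-0.5, 0.2, 0.5, 0.9),
                   function(th) nrow(points_from_density(g, th)$coords),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(points_from_density(g, 2), "no voxel")
  ## mass scaling to a stated total
  pm <- points_from_density(g, 0.5, total_mass = 5000)
  expect_equal(sum(pm$masses), 5000, tolerance = 1e-9)
  ## alpha-shape volume of the thresholded cloud ~ eroded ball
  vol <- shape_volume(build_alpha_shape(pts, alpha = 2))
  expect_equal(vol, 4 / 3 * pi * (6 - 1 / 3)^3, tolerance = 0.1)
})

test_that("mode writers round-trip NMD and produce periodic trajectories", {
  ps <- make_lattice(3)
  mesh <- build_alpha_shape(ps, alpha = 10)
  md <- solve_modes(assemble(mesh, elastic_params()), n_modes = 12)
  f <- withr::local_tempfile(fileext = ".nmd")
  write_modes(ps, md, f, "nmd", modes = 7:9)
  back <- read_nmd(f)
  expect_equal(back$coordinates, ps$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(back$modes, md$vectors[, 7:9], tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(back$wavenumbers, md$wavenumbers[7:9], tolerance = 1e-4)
  ## trajectory: frame 1 = input; first = last over a full period
  ft <- withr::local_tempfile(fileext = ".pdb")
  write_modes(ps, md, ft, "pdb", modes = 7, amplitude = 1.5, n_frames = 9)
  xyz <- bio3d::read.pdb(ft, multi = TRUE, verbose = FALSE)$xyz
  expect_identical(nrow(xyz), 9L)
  expect_equal(max(abs(xyz[1, ] - xyz[9, ])), 0)
  expect_equal(matrix(xyz[1, ], ncol = 3, byrow = TRUE), ps$coords,
               tolerance = 1e-3, ignore_attr = TRUE)
  ## zero amplitude: all frames equal the input
  f0 <- withr::local_tempfile(fileext = ".pdb")
  write_modes(ps, md, f0, "pdb", modes = 7, amplitude = 0, n_frames = 5)
  xyz0 <- bio3d::read.pdb(f0, multi = TRUE, verbose = FALSE)$xyz
  expect_equal(max(abs(sweep(xyz0, 2, xyz0[1, ]))), 0)
  ## CSV table carries eigenvalues and wavenumbers exactly
  fc <- withr::local_tempfile(fileext = ".csv")
  write_modes(ps, md, fc, "csv")
  tab <- utils::read.csv(fc)
  expect_equal(tab$eigenvalue, md$values, tolerance = 1e-12)
  expect_equal(tab$wavenumber_cm1, md$wavenumbers, tolerance = 1e-12)
  expect_error(write_modes(ps, md, tempfile(), "nmd", modes = 99),
               "out of range")
})

test_that("point sets survive a PDB write/read cycle", {
  ps <- make_helix(20)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_points_pdb(ps, f)
  s <- read_structure(f)
  back <- select_nodes(s, "calpha")
  expect_equal(back$coords, ps$coords, tolerance = 1e-3,
               ignore_attr = TRUE)
})
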