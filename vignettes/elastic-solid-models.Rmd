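---
title: "Elastic solid models of macromolecules from alpha shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic solid models of macromolecules from alpha shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aesm)
```

## The model

Elastic network models describe a macromolecule as point masses joined by
springs.  This package implements the complementary picture: the molecule is
a homogeneous, isotropic **elastic solid** whose shape is taken seriously.
The shape is captured by the **alpha shape** of the node coordinates
(C-alpha atoms, all heavy atoms, or voxels of a density map above a
threshold): the Delaunay tetrahedralization is computed, and only those
tetrahedra whose circumsphere radius is at most `alpha` are kept.  The
parameter `alpha` plays the role of the cutoff distance in a network model;
the kept tetrahedra are at once the geometric body of the molecule and the
elements of a finite-element discretization.

Over each tetrahedral element the package assembles the standard
constant-strain linear elasticity matrices.  The material is described by a
Young's modulus $E$ and Poisson ratio $\nu$ through the Lamé parameters

$$\lambda = \frac{\nu E}{(1+\nu)(1-2\nu)}, \qquad \mu = \frac{E}{2(1+\nu)},$$

and a uniform mass density $\rho$.  The global stiffness matrix
$\mathbf{K}$ ($3N \times 3N$) and the consistent mass matrix
$\mathbf{M}$ (assembled as an $N \times N$ scalar matrix and expanded by a
Kronecker product with $I_3$) define the generalized eigenproblem

$$\mathbf{K} v_k = \lambda_k \mathbf{M} v_k ,$$

whose solutions are the normal modes.  A free connected solid has exactly
six zero eigenvalues (rigid translations and rotations); everything else is
an internal vibration with wavenumber
$\omega_k = \sqrt{\lambda_k}/(2\pi c)$ in cm$^{-1}$.

Downstream of the eigenproblem the package provides thermal mean-square
fluctuations and B-factors, least-squares calibration of $E$ against an
experimental B-factor column, vibrational spectra with a power-law fit of
the cumulative mode fraction $G(\omega)$, overlaps of conformational
changes with the mass-weighted modes, linear static response to external
forces, a linearized indentation surrogate for AFM stiffness calibration,
and shape-preserving coarse-graining.  A minimal anisotropic network model
(ANM) is included as the baseline the solid model is usually compared
against.

## Units and conversion factors

All lengths are Angstrom, energies kcal/mol, masses amu.  Consequently $E$
is in kcal mol$^{-1}$ Å$^{-3}$ (multiply by about 6.95 to get GPa) and
eigenvalues of $(\mathbf{K}, \mathbf{M})$ are in
kcal mol$^{-1}$ amu$^{-1}$ Å$^{-2}$.  The wavenumber conversion
$\omega = \sqrt{\lambda_{\mathrm{SI}}}/(2\pi c)$ then reduces to
$\omega \approx 108.59 \sqrt{\lambda}$; the factor is derived from SI
constants at load time rather than hard-coded, and `unit_constants()`
exposes it.  The Boltzmann constant is 0.0019872 kcal mol$^{-1}$ K$^{-1}$
and the default temperature 298 K.

Because $\mathbf{K}$ is strictly proportional to $E$, modes are solved at
$E = 1$ and $E$ is treated as an external scale thereafter: fluctuations are
proportional to $T/E$, so `calibrate_young_modulus()` fits the single scale
that matches predicted to experimental B-factors
($E = \sum P^2 / \sum P B$ for the unit-modulus prediction $P$), and
calibrated wavenumbers are the unit-modulus wavenumbers times $\sqrt{E}$.

## Parameters that matter

* **`alpha` (Å).**  The only shape parameter.  For C-alpha models, 8–10 Å
  is a sensible range (for comparison, ANM conventionally uses a 13 Å
  cutoff); the package defaults to the *critical alpha* — the smallest
  value that encloses every input point — when no value is given.  For a
  coarser node set the value should be adjusted so the solid volume is
  unchanged; `alpha_for_volume()` automates this by exact enumeration of
  the stepwise volume-versus-alpha function (the volume only jumps at the
  circumradius values of the Delaunay cells, so no iterative bisection is
  needed and the smallest alpha on the matching plateau is returned).
* **`E` (kcal mol$^{-1}$ Å$^{-3}$).**  Global stiffness scale; calibrated,
  not chosen.  Proteins come out at a few GPa.
* **`nu`.**  Poisson ratio, default 0.3, the conventional choice for
  proteins; results depend on it only weakly.
* **`rho` (amu Å$^{-3}$).**  By default derived as (total node mass)/(solid
  volume), so the model's total mass equals the molecule's mass and
  absolute frequencies are physically scaled.  C-alpha nodes carry their
  residue's average mass, heavy-atom nodes their element mass, and
  density-derived nodes masses proportional to voxel density.

## Numerical choices

**Degenerate Delaunay cells.**  Exact lattices (our test fixtures) contain
cospherical and coplanar point groups for which the Delaunay
tetrahedralization is not unique and flat cells appear.  The package
restores general position with a deterministic, input-independent jitter of
amplitude $10^{-8}$ of the bounding box, used only for the triangulation
and the circumradius *filter*; volumes, node coordinates and all physics
use the original coordinates exactly.  Cells with original-coordinate
volume below `sliver_tol` ($10^{-9}$ Å$^3$) are excluded from the element
list — a flat element would be singular — but retained in the complex for
boundary and connectivity purposes, where they glue their neighbours
together and keep the boundary surface watertight.  With a different
triangulation backend, results can differ only in such zero-measure
configurations.

**Eigensolver.**  Systems up to 1800 degrees of freedom are solved densely
through the Cholesky factor of $\mathbf{M}$; larger systems use a
shift-invert Krylov iteration on the sparse matrices (the operator
$(\mathbf{K}+\sigma\mathbf{M})^{-1}\mathbf{M}$ with a small positive
$\sigma$), followed by Gram–Schmidt re-orthonormalization in the
$\mathbf{M}$ inner product.  The two paths agree to $10^{-9}$ on the test
systems.  Rigid modes are flagged by $\lambda < 10^{-8}\,\lambda_{\max}$.

**Overlaps.**  Conformational displacements are superposed (least-squares
rigid fit) before differencing — a projection onto internal modes is
meaningless while a rigid offset remains — and projected onto the
mass-weighted modes $q_k = \mathbf{M}^{1/2} v_k$, which form a complete
orthonormal basis (Parseval: $\sum_k O_k^2 = 1$).  Mode indices in reports
count from the first non-rigid mode, and $N_{\sigma 90}$ is the smallest
$m$ with $\sum_{k\le m} O_k^2 \ge 0.9$; the cumulative-variance convention
is stated here explicitly because different packages inherit slightly
different definitions.

**Power-law fit window.**  The exponent of $G(\omega) \propto \omega^p$ is
fitted by ordinary least squares in log–log space over the modes below the
median wavenumber; the low-frequency half is where the power law is
expected to hold, and the choice is fixed rather than tuned.

**Indentation surrogate.**  The AFM indentation stiffness per unit modulus,
$\kappa_{\mathrm{cal}}$, is computed by a *linear* surrogate: the spherical
tip is placed tangent to the topmost node, pushed in by a stated depth, and
every node inside the geometric footprint receives the prescribed
displacement of the sphere surface while the base ring is fixed; the slope
(reaction force / depth / $E$) is $E$-independent because
$\mathbf{K} \propto E$.  A full nonlinear contact simulation is outside the
scope of this package (the mesh exporters exist precisely so that such runs
can be done in a dedicated FEA program); in the small-indentation limit the
two coincide, but quantitative agreement with a nonlinear contact run is
only order-of-magnitude.  The measured stiffness $k_{\mathrm{exp}}$ (nN/nm)
then gives $E = k_{\mathrm{exp}}/\kappa_{\mathrm{cal}}$ in GPa.

**Coarse-graining.**  `coarsen_structure()` peels the solid layer by layer:
boundary nodes of the current alpha shape are reduced by quadric
edge-collapse decimation of the surface mesh, the layer is removed, and the
procedure recurses; interior points that remain after the final layer are
voxel-downsampled to the same fraction.  Two choices depart from generic
mesh simplifiers.  First, decimated vertices are snapped back to their
nearest original nodes, so the coarse model's nodes are a strict subset of
the input coordinates — re-meshing that invents new nodes would break the
property that modes live directly on the structure's own points.  Second,
interior downsampling is grid-based with a seeded representative choice,
so identical inputs and seed give identical output.  Peeling stops when the
interior has fewer than four points or `n_layers` is reached; layers too
small for edge collapse fall back to the voxel downsampler.

## What the synthetic fixtures do and do not show

The package is exercised end to end on deterministic fixtures: cubic
lattices (known exact volumes, 8/27/… unit cells), rectangular bars (the
continuum limit of the fundamental axial frequency,
$\omega = \tfrac{1}{2L}\sqrt{E/\rho}$, is a closed form), spherical shells
(indentation and spectrum), an ideal helix, and binary sphere density maps.
These validate the geometry, the assembly, the eigensolver, the statics and
the coarse-graining against independent oracles and closed forms.

They do not emulate real protein packing: there is no heterogeneity of
local density, no surface roughness statistics, no experimental noise in
B-factors, and lattice symmetry is atypically degenerate (which is exactly
why the fixtures are good stress tests for the triangulation).  Passing
these tests shows the machinery is correct, not that any particular protein
will be predicted well; the structure-dependent reproductions (calibrated
modulus, lowest wavenumber, overlap benchmarks) require the corresponding
PDB entries, which must be supplied by the user.

Two subtleties in the bar fixture are worth recording.  The closed form
$\tfrac{1}{2L}\sqrt{E/\rho}$ is one-dimensional rod theory, which is the
exact continuum limit only at $\nu = 0$; at $\nu = 0.3$ the finite bar sits
within a couple of percent of it.  And in a slender free–free bar the axial
branch is embedded among many near-degenerate bending modes, so the
discrete axial-dominant eigenvector hybridizes at the percent level;
`axial_wavenumber()` therefore also reports the projection-weighted modal
average (the Rayleigh quotient of the interpolated axial pattern), which is
the stable estimator used for the convergence study (run at $\nu = 0$, mesh
sizes 117, 625 and 1813 nodes).

## Problem sizes

The shipped tests and the acceptance script run on fixtures between 27 and
about 1800 nodes (up to roughly 5400 degrees of freedom), chosen so the
dense and sparse eigenpaths, the cell-list contact search and the layered
coarse-graining are all exercised; the same code paths scale to
tens of thousands of nodes through the sparse solver, where only the
requested low-frequency modes are computed.

## Known limitations

* Only 3-simplices are kept (no edge/triangle alpha complex), matching the
  solid-model use of the shape; cavities and pockets are not detected.
* Linear kinematics throughout: no buckling, no large deformations, no
  contact.  The indentation number is a linearized surrogate.
* The MRC reader covers modes 0/1/2 with axis-order normalization; exotic
  header variants are out of scope.
* Assembly-operator expansion handles explicit BIOMT matrices only; no
  space-group inference.
* The quadric decimator is greedy and pass-based; it preserves shape well
  at the fractions used here but is not guaranteed optimal for extreme
  reductions.

## A compact example

```{r example, eval = FALSE}
ps <- make_lattice(5)                     # 125 nodes, unit spacing
mesh <- build_alpha_shape(ps, alpha = 3)  # 64 A^3 cube, exactly
sys <- assemble(mesh, elastic_params(E = 1, nu = 0.3))
modes <- solve_modes(sys, n_modes = 26)
modes                                     # 6 rigid + 20 vibrations
fluct <- mean_square_fluctuations(modes, E = 1, T_K = 298)
head(fluct)
```
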