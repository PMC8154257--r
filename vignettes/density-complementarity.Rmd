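---
title: "Electron-density complementarity scoring of binding poses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-density complementarity scoring of binding poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denscomp)
```

## The model

A protein--ligand complex binds well when the electron clouds of the two
partners fill the intermolecular space in a complementary way. `denscomp`
quantifies this with a *promolecular* density: each atom contributes a
spherically averaged, non-interacting density built from normalised radial
Slater functions,

$$\rho_A(r) \;=\; \sum_{\text{shells}} \mathrm{occ}
  \,\frac{(2\zeta)^{2n+1}}{(2n)!\,4\pi}\, r^{2n-2} e^{-2\zeta r},$$

with $r$ and $\zeta$ in atomic units internally and everything user-facing
in Angstrom. By construction each shell integrates to its occupancy, so an
element's density integrates exactly to its atomic number -- the package
asserts this per element by quadrature. Molecular densities are plain
superpositions of atomic terms; there is no charge relaxation, no angular
structure, and no distinction between bonded and free atoms. These are the
standard promolecule approximations; their virtue here is that the
logarithm of an atomic tail is asymptotically *linear* in distance, which
is what makes the scoring law below work.

Densities are evaluated on a cubic grid of 0.1 A spacing (1000 points per
cubic Angstrom) spanning the ligand bounding box plus a 3 A margin. A grid
point is an **overlap point** when the ligand density and the receptor
density both reach `rho_min` (default 0.001 e/A^3). For every overlap
point $m$ the package records the highest-contributing atom of each
molecule, the distances to them, and

$$\mathrm{SUMDLE}_m = d_{\text{ligand}} + d_{\text{enzyme}}, \qquad
  y_m = \ln(\rho_{\text{ligand}}\rho_{\text{enzyme}}) + \rho_N,$$

where $\rho_N = \ln(N_L N_E) - \ln(\rho_{LC}\,\rho_{EC})$ is built from
the atomic numbers and the centre densities of the two top-contributing
atoms. Ordinary least squares of $y$ on SUMDLE gives the
**complementarity line**

$$y = b + a\,\mathrm{SUMDLE},$$

with $a$ in 1/A and $b$ dimensionless (log arguments are divided by
1 e/A^3 implicitly). The slope reflects binding efficiency: reference
(crystallographic or energy-minimised) poses of one receptor cluster
tightly in $(a, b)$, while corrupted poses scatter; and $a$ and $b$ are
nearly collinear across poses, so the slope alone classifies a pose.

### Why this form of the normalisation term

The rendered source equations for $\rho_N$ are not available in algebraic
form, so the package adopts the unique expression consistent with the
per-molecule split
$\sigma_{\text{ligand}} = \ln(\rho_{\text{ligand}} N_L/\rho_{LC})$,
$\sigma_{\text{enzyme}} = \ln(\rho_{\text{enzyme}} N_E/\rho_{EC})$ and the
identity $y = \sigma_{\text{ligand}} + \sigma_{\text{enzyme}}$, which
`overlap_points()` asserts to 1e-10 at every point. The term is isolated
in one internal function so an alternative algebraic form can be swapped
without touching the pipeline. Centre densities $\rho_{LC}, \rho_{EC}$
default to the *molecular* density at the atom centre (neighbour tails
included); `density_model(center_mode = "isolated")` switches to the bare
atomic value, since the source description ("density in the centre of the
highest-contributing atom") does not resolve the choice.

## The analytic limit that anchors the tests

For two atoms that each carry a single 1s shell with a common exponent
$\zeta$, the ratios $\rho/\rho_C$ are pure exponentials and every overlap
point satisfies *exactly*

$$y = \ln(Z_L Z_E) - 2\zeta\,\mathrm{SUMDLE},$$

so the fitted slope must be $a = -2\zeta/a_0$ per Angstrom (with $a_0$ the
Bohr radius) and $b = \ln(Z_L Z_E)$, with $R^2 = 1$, for *any* geometry.
`make_single_zeta_pair()` constructs this fixture together with its
expected coefficients; with $\zeta = 1\,\mathrm{bohr}^{-1}$, $Z = 1$ the
pipeline must land on $a \approx -3.7794$ A$^{-1}$, $b = 0$. This is the
package's primary correctness oracle because it exercises the whole chain
-- grid, density, thresholding, top-atom bookkeeping, normalisation,
regression -- against a closed form.

## Parameters that matter

* **Shell table** (`inst/extdata/slater_shells.txt`). The published
  parameterisation this method family uses is not tabulated in the open
  literature, so the defaults are Clementi--Raimondi single-zeta
  exponents per occupied subshell (H--Ar) with neutral-atom occupancies,
  extended by Slater's-rules exponents for K, Ca, Fe, Zn, Se, Br and I.
  The file is plain text precisely so an alternative table can be dropped
  in (`density_model(file = ...)`); all structural conclusions in the
  package's tests rest on closed forms that hold for any positive
  exponents.
* **`rho_min` = 0.001 e/A^3.** The inclusion rule for "overlapping
  clouds" is a dual threshold on both contributions -- the minimal
  assumption consistent with partial cloud overlap. Lowering it only
  appends weaker points with larger SUMDLE (a tested invariant).
* **Grid spacing 0.1 A, margin 3 A.** Spacing matches the stated
  sampling density of the method; the margin covers the SUMDLE range
  (roughly 8 A total) seen in practice. Grid nodes sit on the *absolute*
  lattice `k * spacing`: enlarging the box (say, a remote substituent
  atom is added) never moves existing nodes, which is why fits are
  exactly invariant to protruding groups outside the overlap region.
* **Contribution cutoff 10 A**: single-zeta tails there are below 1e-9
  of centre values for all shipped elements.
* **Hydrogens** contribute by default (`include_hydrogens = TRUE`);
  heavy-atom-only mode exists because input hydrogens are often absent or
  unreliable. RMSD comparisons ignore hydrogens by default for the same
  reason.
* **FOF threshold = grid spacing.** Contact clustering is single-linkage
  friends-of-friends; at the default threshold on grid points it equals
  6-neighbour connected-component labelling. Diagonal neighbours
  (0.1 sqrt(2) A apart) are deliberately *not* linked; a 26-connectivity
  flag exists for sensitivity analysis. Cluster numbering is
  deterministic: by decreasing size, ties broken by the lexicographically
  smallest grid index.
* **Envelope mode.** The reference envelope is the min--max rectangle of
  the reference $(a, b)$ values; classification uses the closed slope
  interval $[a_{\min}, a_{\max}]$ (mean +/- 2 sd optionally). A pose
  inside the envelope but far in RMSD from the reference is reported as a
  candidate alternative/metastable pose, not an error.

## Numerical choices and degenerate inputs

Ties for the highest-contributing atom break to the lower serial; output
ordering is lexicographic in the grid index; exports format numbers to six
significant digits so reruns are byte-identical. Fits require at least
three points and two distinct SUMDLE values, envelopes at least two
references, the intercept-versus-slope line at least three fits; poses
whose clouds never reach `rho_min` raise a dedicated no-overlap error that
the batch runner records per pose instead of aborting. The Hungarian
assignment for symmetry-corrected RMSD is solved exactly per element class
(shortest augmenting paths); element classes -- not bond-topology
automorphisms -- define the allowed matchings, and no superposition is
ever applied, because docked and reference poses already share the
receptor frame.

## What the synthetic generators emulate -- and what they do not

`make_single_zeta_pair()` gives exact regression coefficients;
`make_pose_ensemble()` gives exact RMSD ground truths (displacement norms,
within-element permutations); `make_clustered_points()` gives exact
component counts; `make_rotated_substituent_pair()` mimics a flexible
group flipping 180 degrees outside a binding pocket (plain RMSD jumps by
more than 1 A, the contact-forming core is untouched);
`make_displacement_series()` pushes a one-atom ligand from the centre of a
four-carbon pocket toward a wall. In that series the multi-shell
log-density profile -- flat near the nucleus, steepening outward -- makes
poses pressed against a wall sample the flat region, so the fitted slope
rises toward zero and the intercept falls monotonically with displacement
(displacements 0--2 A against a 3.5 A pocket radius; beyond that the trend
saturates as the ligand sits on top of the wall atom). Only the centred
pose classifies inside an envelope built from the centred pose and two
0.1 A in-plane jitters.

None of these fixtures have conformational flexibility, solvent,
protonation chemistry, or realistic pocket shapes. Passing tests therefore
demonstrate that the *method* is implemented correctly (closed forms,
oracles, invariants), not that the default parameterisation reproduces
published per-complex coefficients on real PDB structures -- that would
require the original atomic parameters and the original
minimisation/docking protocol. On real systems one should expect the
qualitative behaviour (tight reference envelopes, slope-based separation
of corrupted poses, near-collinear $a$--$b$) rather than identical
coefficient values; on the displacement fixture the collinearity comes out
at adjusted $R^2 \approx 0.999$.

## Problem sizes

The test-suite and acceptance runs use two-atom fixtures on roughly
220k-node grids (about 3000 overlap points, under a second each), a
six-atom pocket series (about 2 s), 200-point clustering oracles and
eight-atom exhaustive RMSD enumerations. These sizes keep every oracle
exact (brute-force enumeration stays feasible) while exercising the same
code paths a receptor-scale run would use; `overlap_points()` evaluates
the cheap ligand pass over the full grid first and the receptor pass only
at surviving candidates, so receptor size enters only linearly.

## Known limitations

* No mmCIF/MOL2/SDF input, no protonation or structure repair: poses are
  expected as pre-aligned PDB files.
* Promolecular densities only -- no charge transfer, no anions/cations,
  no d/f angular structure, no inner-shell overlap (Pauli) diagnostics.
* The slope ranks poses; converting it into an absolute binding constant
  is out of scope.
* Weighted or robust regression variants and per-cluster fits are not
  provided; clusters are summarised, not separately fitted.
* The toolkit is built for in-depth analysis of a handful of poses, not
  for virtual-screening throughput.
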