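## Synthetic fixtures with analytically known answers.
##
## The single-exponent pair is the analytic limit of the complementarity
## law: for two atoms carrying one 1s Slater shell with a common exponent
## zeta (bohr^-1), every overlap point satisfies exactly
##
##   y = ln(Z_L * Z_E) - 2 * zeta * SUMDLE          (zeta in the same
##                                                   length unit as SUMDLE)
##
## so the fitted slope is a = -2 * zeta / a0 per Angstrom and the
## intercept b = ln(Z_L * Z_E), with R^2 = 1 regardless of separation.
## Pseudo-elements used here never ship in the default parameter table.

## run expr under a temporary seed without disturbing global RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Single-exponent two-atom complex with known coefficients
#'
#' One pseudo-atom per molecule, each a single 1s Slater shell with the
#' same exponent, so the end-to-end pipeline must recover the analytic
#' line exactly (see the fixture notes above).
#'
#' @param zeta Common shell exponent in bohr^-1.
#' @param Z Atomic number (= shell occupancy) of both pseudo-atoms.
#' @param separation Distance between the two atoms in Angstrom. The
#'   clouds must still overlap at the model's `rho_min`: with the defaults
#'   (`zeta = 1`, `Z = 1`) that holds out to about 4 A; softer or heavier
#'   pseudo-atoms (smaller `zeta`, larger `Z`) extend the range.
#' @return List with `receptor`, `ligand` ([molecule_pose()]s), `model`
#'   (a [density_model()] knowing the pseudo-element `"Q"`), and
#'   `expected` (`a` in A^-1, `b`, `r2`).
#' @export
make_single_zeta_pair <- function(zeta = 1.0, Z = 1L, separation = 3.0) {
  if (zeta <= 0) .stopf("zeta must be positive")
  if (separation <= 0) .stopf("separation must be positive")
  extra <- stats::setNames(as.integer(Z), "Q")
  shells <- data.frame(element = "Q", n = 1L, zeta = zeta, occupancy = Z)
  model <- density_model(extra_shells = shells, extra_elements = extra)
  receptor <- molecule_pose("Q", matrix(c(0, 0, 0), 1), name = "Q1",
                            resname = "REC", is_hetero = FALSE,
                            label = "pair_receptor", extra_elements = extra)
  ligand <- molecule_pose("Q", matrix(c(separation, 0, 0), 1), name = "Q1",
                          resname = "LIG", label = "pair_ligand",
                          extra_elements = extra)
  list(receptor = receptor, ligand = ligand, model = model,
       expected = list(a = -2 * zeta / BOHR_A, b = 2 * log(Z), r2 = 1))
}

#' Pose ensemble with known RMSD ground truth
#'
#' A random reference pose plus copies that are rigidly displaced (exact
#' RMSD = displacement norm), permuted within element classes (Hungarian
#' RMSD exactly 0) and optionally jittered (naive RMSD recorded from the
#' drawn perturbations). Deterministic under `seed`.
#'
#' @param n_atoms Number of atoms in the reference pose.
#' @param elements Element symbols to draw from (recycled/sampled).
#' @param displacements Numeric vector of rigid displacement norms (A).
#' @param n_permuted Number of within-element permutation copies.
#' @param jitter_sd If positive, adds one jittered copy with this
#'   per-coordinate Gaussian sd (A).
#' @param seed Integer seed fixing all randomness.
#' @return List with `poses` (named list of [molecule_pose()]; first is
#'   `"reference"`) and `truth` (data frame `label`, `variant`, `rmsd`
#'   where `rmsd` is the known value for that variant: displacement norm
#'   for displaced copies under either variant, 0 for permuted copies
#'   under the Hungarian variant, the drawn perturbation RMS for the
#'   jittered copy under the naive variant).
#' @export
make_pose_ensemble <- function(n_atoms = 8, elements = c("C", "C", "C", "N", "O"),
                               displacements = c(1, 2), n_permuted = 1,
                               jitter_sd = 0, seed = 1) {
  .with_seed(seed, {
    el <- sample(elements, n_atoms, replace = TRUE)
    ## rejection-sample a cluster with >= 1 A separation so poses are valid
    repeat {
      xyz <- matrix(stats::runif(n_atoms * 3, 0, 4), ncol = 3)
      if (n_atoms == 1L || min(stats::dist(xyz)) >= 1.0) break
    }
    ref <- molecule_pose(el, xyz, label = "reference")
    poses <- list(reference = ref)
    truth <- data.frame(label = character(0), variant = character(0),
                        rmsd = numeric(0), stringsAsFactors = FALSE)
    for (d in displacements) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      lab <- sprintf("displaced_%g", d)
      poses[[lab]] <- molecule_pose(el, xyz + rep(d * u, each = n_atoms),
                                    label = lab)
      truth <- rbind(truth, data.frame(label = lab, variant = "any", rmsd = d))
    }
    for (k in seq_len(n_permuted)) {
      perm <- seq_len(n_atoms)
      for (e in unique(el)) {
        idx <- which(el == e)
        if (length(idx) > 1L) perm[idx] <- sample(idx)
      }
      lab <- sprintf("permuted_%d", k)
      poses[[lab]] <- molecule_pose(el[perm], xyz[perm, , drop = FALSE],
                                    label = lab)
      truth <- rbind(truth, data.frame(label = lab, variant = "hungarian",
                                       rmsd = 0))
    }
    if (jitter_sd > 0) {
      delta <- matrix(stats::rnorm(n_atoms * 3, 0, jitter_sd), ncol = 3)
      poses$jittered <- molecule_pose(el, xyz + delta, label = "jittered")
      truth <- rbind(truth, data.frame(label = "jittered", variant = "naive",
                                       rmsd = sqrt(mean(rowSums(delta^2)))))
    }
    list(poses = poses, truth = truth)
  })
}

#' Grid-aligned point blobs with a known component count
#'
#' Generates `n_blobs` solid lattice boxes, consecutive blobs separated by
#' at least `gap` along x, so friends-of-friends clustering at
#' `threshold = spacing` must find exactly `n_blobs` clusters.
#'
#' @param n_blobs Number of blobs.
#' @param gap Minimum blob separation in Angstrom (`gap > spacing`).
#' @param spacing Lattice spacing in Angstrom.
#' @param seed Integer seed.
#' @return Data frame with `ix`, `iy`, `iz`, `x`, `y`, `z` and a
#'   `blob` column (the generating blob); attribute
#'   `expected_clusters = n_blobs`, and a `grid` attribute so
#'   [cluster_contacts()] picks up the spacing.
#' @export
make_clustered_points <- function(n_blobs = 3, gap = 0.5, spacing = 0.1,
                                  seed = 1) {
  if (gap <= spacing) .stopf("gap must exceed spacing")
  .with_seed(seed, {
    gap_cells <- ceiling(gap / spacing) + 1L
    out <- list()
    x0 <- 0L
    for (bl in seq_len(n_blobs)) {
      k <- sample(1:3, 3, replace = TRUE)   # blob extents in cells
      oy <- sample(0:5, 1); oz <- sample(0:5, 1)
      idx <- expand.grid(ix = x0 + seq_len(k[1]) - 1L,
                         iy = oy + seq_len(k[2]) - 1L,
                         iz = oz + seq_len(k[3]) - 1L)
      idx$blob <- bl
      out[[bl]] <- idx
      x0 <- x0 + k[1] + gap_cells
    }
    pts <- do.call(rbind, out)
    pts$x <- pts$ix * spacing
    pts$y <- pts$iy * spacing
    pts$z <- pts$iz * spacing
    attr(pts, "expected_clusters") <- n_blobs
    attr(pts, "grid") <- structure(
      list(origin = c(0, 0, 0), spacing = spacing,
           shape = c(max(pts$ix), max(pts$iy), max(pts$iz)) + 1L),
      class = "grid_spec")
    pts
  })
}

#' Core-plus-substituent pose pair with a rotated substituent
#'
#' A rigid core (the part forming contacts) plus a protruding three-atom
#' substituent; the second pose is identical except that the substituent
#' is rotated 180 degrees about its attachment axis, mimicking a flexible
#' group flipping outside the binding pocket. The rotation inflates the
#' plain RMSD while leaving the contact-forming core untouched.
#'
#' @return List with `pose`, `rotated`, and `substituent_serials` (the
#'   serials to pass as `exclude` to [symmetry_rmsd()]).
#' @export
make_rotated_substituent_pair <- function() {
  el <- c("C", "O", "N", "C", "C", "O")
  core <- rbind(c(0, 0, 0), c(1.25, 0.6, 0), c(0.4, -1.3, 0.2))
  sub <- rbind(c(-1.45, 0.85, 0.3), c(-2.75, 0.9, 1.0), c(-3.6, -0.4, 0.8))
  pose <- molecule_pose(el, rbind(core, sub), label = "substituent_ref")
  ## 180 degree rotation about the x-axis through the attachment atom
  sub_rot <- cbind(sub[, 1], -sub[, 2], -sub[, 3])
  rotated <- molecule_pose(el, rbind(core, sub_rot),
                           label = "substituent_flipped")
  list(pose = pose, rotated = rotated, substituent_serials = 4:6)
}

#' Write a single-exponent pair fixture to disk
#'
#' Serialises the [make_single_zeta_pair()] poses as PDB files plus a
#' ground-truth manifest, so the analytic coefficients can be checked on
#' file-based runs (and from the command line).
#'
#' @param dir Output directory (created if missing).
#' @param zeta,Z,separation Passed to [make_single_zeta_pair()].
#' @return Invisibly, the manifest list; writes `receptor.pdb`,
#'   `ligand.pdb`, a `params.txt` shell table for the pseudo-element and
#'   `manifest.json` into `dir`.
#' @export
write_pair_fixture <- function(dir, zeta = 1.0, Z = 1L, separation = 3.0) {
  pair <- make_single_zeta_pair(zeta = zeta, Z = Z, separation = separation)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pose(pair$receptor, file.path(dir, "receptor.pdb"))
  write_pose(pair$ligand, file.path(dir, "ligand.pdb"))
  writeLines(c("# single-exponent pseudo-element shell",
               sprintf("Q  1  %.10g  %d", zeta, Z)),
             file.path(dir, "params.txt"))
  manifest <- list(zeta = zeta, Z = Z, separation = separation,
                   pseudo_element = "Q", parameter_file = "params.txt",
                   expected = pair$expected)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(manifest)
}

#' Displacement series of a ligand pushed off its pocket centre
#'
#' A fixed receptor pocket (four carbon atoms forming a 3.5 A-radius ring)
#' with a single nitrogen ligand at the centre; copies of the ligand are
#' displaced laterally toward one wall by the given amounts. With the
#' default multi-shell parameters the log-density profile of an atom is
#' curved (flat near the nucleus, steepening outward), so a pose pressed
#' against a wall samples the flat part and its fitted slope `a` rises
#' toward zero while the intercept `b` falls -- the synthetic analogue of
#' corrupted docking poses scattering away from the reference envelope.
#'
#' @param displacements Numeric vector of lateral displacements in
#'   Angstrom (0 = centred reference geometry; the wall sits at 3.5 A, so
#'   values up to about 2 keep a clear monotone trend).
#' @param model A [density_model()]; default parameters.
#' @return List with `receptor`, `ligands` (named list, labels
#'   `disp_<d>`), `references` (the centred pose plus two 0.1 A in-plane jittered
#'   copies, mimicking crystallographic/minimised references),
#'   `displacements`, `model`.
#' @export
make_displacement_series <- function(displacements = c(0, 0.5, 1, 1.5, 2),
                                     model = density_model()) {
  r <- 3.5
  rec_xyz <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0))
  receptor <- molecule_pose(rep("C", 4), rec_xyz, name = paste0("C", 1:4),
                            resname = "REC", is_hetero = FALSE,
                            label = "pocket")
  mk <- function(xyz, lab) molecule_pose("N", matrix(xyz, 1), name = "N1",
                                         label = lab)
  ligands <- list()
  for (d in displacements) {
    lab <- sprintf("disp_%g", d)
    ligands[[lab]] <- mk(c(d, 0, 0), lab)
  }
  references <- list(ref_0 = mk(c(0, 0, 0), "ref_0"),
                     ref_jit1 = mk(c(0.1, 0, 0), "ref_jit1"),
                     ref_jit2 = mk(c(0, -0.1, 0), "ref_jit2"))
  list(receptor = receptor, ligands = ligands, references = references,
       displacements = displacements, model = model)
}
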