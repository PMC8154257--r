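## Promolecular electron density from Slater-type atomic contributions.
##
## Each atom contributes a spherically averaged density built from
## normalised radial Slater functions R_{n,zeta}(r) ~ r^(n-1) exp(-zeta r):
##
##   rho_atom(r) = sum_shells occ * (2 zeta)^(2n+1) / (2n)! *
##                 r^(2n-2) exp(-2 zeta r) / (4 pi)        [e/bohr^3]
##
## which integrates exactly to the shell occupancy, so the per-element
## density integrates to the atomic number by construction. Molecular
## (promolecular) density is the plain superposition of atomic terms.

#' Build a density model from a Slater shell parameter table
#'
#' @param file Whitespace-delimited parameter file with columns
#'   `element`, `n`, `zeta` (bohr^-1), `occupancy`; defaults to the
#'   Clementi-Raimondi single-zeta table shipped with the package.
#' @param include_hydrogens Should hydrogen (and deuterium) atoms
#'   contribute to molecular densities? Default `TRUE`; heavy-atom-only
#'   mode is useful when input hydrogens are unreliable.
#' @param rho_min Overlap inclusion threshold in e/A^3 (default 0.001):
#'   a grid point is an overlap point when both the ligand and the
#'   receptor density reach this value.
#' @param cutoff Distance (Angstrom) beyond which an atom's contribution
#'   is treated as zero (default 10; single-zeta tails there are < 1e-9
#'   of center values for all shipped elements).
#' @param center_mode `"molecular"` (default) evaluates the center
#'   densities rho_LC / rho_EC as the molecule's total density at the atom
#'   center (neighbour tails included); `"isolated"` uses the isolated-atom
#'   value.
#' @param extra_shells Optional data frame (`element`, `n`, `zeta`,
#'   `occupancy`) of additional -- possibly pseudo -- elements, appended to
#'   the table (fixtures use this; pseudo-elements never enter the default
#'   table).
#' @param extra_elements Named integer vector of atomic numbers for the
#'   pseudo-element symbols in `extra_shells`.
#' @return An object of class `density_model`.
#' @export
density_model <- function(file = NULL, include_hydrogens = TRUE,
                          rho_min = 0.001, cutoff = 10,
                          center_mode = c("molecular", "isolated"),
                          extra_shells = NULL, extra_elements = NULL) {
  center_mode <- match.arg(center_mode)
  if (is.null(file))
    file <- system.file("extdata", "slater_shells.txt", package = "denscomp")
  tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                           col.names = c("element", "n", "zeta", "occupancy"),
                           stringsAsFactors = FALSE)
  if (!is.null(extra_shells)) {
    extra_shells <- extra_shells[, c("element", "n", "zeta", "occupancy")]
    tab <- rbind(tab, extra_shells)
  }
  if (any(tab$zeta <= 0) || any(tab$occupancy <= 0) || any(tab$n < 1))
    .stopf("invalid shell parameters: zeta and occupancy must be positive, n >= 1")
  shells <- split(tab[, c("n", "zeta", "occupancy")], tab$element)
  ## occupancies must sum to the atomic number element by element
  for (el in names(shells)) {
    z <- atomic_number(el, extra_elements)
    s <- sum(shells[[el]]$occupancy)
    if (abs(s - z) > 1e-9)
      .stopf("occupancies for %s sum to %g, expected %d", el, s, z)
  }
  structure(
    list(shells = shells, include_hydrogens = include_hydrogens,
         rho_min = rho_min, cutoff = cutoff, center_mode = center_mode,
         extra_elements = extra_elements),
    class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf(
    "density_model: %d elements (%s), rho_min %g e/A^3, cutoff %g A, %s H\n",
    length(x$shells), paste(names(x$shells), collapse = " "),
    x$rho_min, x$cutoff, if (x$include_hydrogens) "with" else "without"))
  invisible(x)
}

.model_shells <- function(model, element) {
  s <- model$shells[[element]]
  if (is.null(s)) .stopf("element '%s' has no density parameters", element)
  s
}

#' Atomic density at a radial distance
#'
#' Spherically averaged single-atom electron density.
#'
#' @param model A [density_model()].
#' @param element Element symbol.
#' @param r Numeric vector of distances in Angstrom (`r >= 0`).
#' @return Density in e/A^3, strictly positive at finite `r`.
#' @export
atomic_density <- function(model, element, r) {
  if (any(r < 0)) .stopf("distances must be non-negative")
  s <- .model_shells(model, element)
  rb <- r / BOHR_A
  rho <- numeric(length(r))
  for (k in seq_len(nrow(s))) {
    n <- s$n[k]; zeta <- s$zeta[k]; occ <- s$occupancy[k]
    norm <- (2 * zeta)^(2 * n + 1) / factorial(2 * n) / (4 * pi)
    term <- if (n == 1L) exp(-2 * zeta * rb) else rb^(2 * n - 2) * exp(-2 * zeta * rb)
    rho <- rho + occ * norm * term
  }
  rho / BOHR_A^3
}

## atoms used for density sums, ordered by serial (tie-break convention:
## the highest contributor with equal contributions is the lowest serial)
.density_atoms <- function(model, pose) {
  keep <- rep(TRUE, nrow(pose))
  if (!model$include_hydrogens) keep <- !(pose$element %in% c("H", "D"))
  idx <- which(keep)[order(pose$serial[keep])]
  if (length(idx) == 0L)
    .stopf("pose '%s' has no atoms contributing to the density", pose_label(pose))
  idx
}

#' Molecular (promolecular) density at arbitrary points
#'
#' Sums atomic contributions over all atoms of one molecule and records,
#' per point, the highest-contributing atom and the distance to it.
#' Contributions beyond the model cutoff are treated as zero.
#'
#' @param model A [density_model()].
#' @param pose A [molecule_pose()].
#' @param points Numeric m x 3 matrix (or length-3 vector) of Cartesian
#'   points, Angstrom.
#' @return A data frame with columns `rho_total` (e/A^3), `top_index`
#'   (row in `pose`), `top_serial`, `top_contribution`, `top_distance` (A).
#'   Points with no atom inside the cutoff get `rho_total = 0` and `NA`
#'   top-atom fields.
#' @export
molecular_density <- function(model, pose, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  atoms <- .density_atoms(model, pose)
  m <- nrow(points)
  rho_total <- numeric(m)
  best <- numeric(m)
  best_i <- rep(NA_integer_, m)
  best_d <- rep(NA_real_, m)
  for (i in atoms) {
    dx <- points[, 1] - pose$x[i]
    dy <- points[, 2] - pose$y[i]
    dz <- points[, 3] - pose$z[i]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    contrib <- atomic_density(model, pose$element[i], d)
    contrib[d > model$cutoff] <- 0
    rho_total <- rho_total + contrib
    upd <- contrib > best
    if (any(upd)) {
      best[upd] <- contrib[upd]
      best_i[upd] <- i
      best_d[upd] <- d[upd]
    }
  }
  data.frame(rho_total = rho_total, top_index = best_i,
             top_serial = pose$serial[best_i],
             top_contribution = best, top_distance = best_d)
}

#' Density at an atom's own center
#'
#' The center density rho_LC / rho_EC entering the normalisation term. In
#' `"molecular"` mode (default) this is the molecule's total density at the
#' atom position, i.e. it includes the tails of neighbouring atoms; in
#' `"isolated"` mode it is the bare atomic value at r = 0.
#'
#' @param model A [density_model()].
#' @param pose A [molecule_pose()].
#' @param serial Atom serial number (must belong to `pose`).
#' @return Density in e/A^3 (scalar).
#' @export
center_density <- function(model, pose, serial) {
  i <- match(serial, pose$serial)
  if (is.na(i)) .stopf("atom serial %s is not in pose '%s'",
                       serial, pose_label(pose))
  if (model$center_mode == "isolated")
    return(atomic_density(model, pose$element[i], 0))
  molecular_density(model, pose, c(pose$x[i], pose$y[i], pose$z[i]))$rho_total
}

## center densities for a set of pose row indices, cached per unique index
.center_densities <- function(model, pose, rows) {
  u <- sort(unique(rows))
  vals <- vapply(u, function(i)
    center_density(model, pose, pose$serial[i]), numeric(1))
  vals[match(rows, u)]
}
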