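## The complementarity regression: grid construction, overlap-point
## selection, per-point descriptors and the ordinary least-squares fit of
##
##   ln(rho_ligand * rho_enzyme) + rhoN = b + a * SUMDLE
##
## where, per overlap point, SUMDLE is the sum of the distances to the
## highest-contributing ligand and receptor atoms and
## rhoN = ln(N_L * N_E) - ln(rho_LC * rho_EC) is built from their atomic
## numbers and center densities. Log arguments are rendered dimensionless
## by an implicit division by 1 e/A^3.

#' Build a sampling grid over the ligand region
#'
#' The grid is the ligand bounding box expanded by `margin` on each side,
#' discretised at `spacing`. Grid nodes lie on the absolute lattice
#' `k * spacing` (the box edges are snapped outward to lattice points), so
#' enlarging the box -- e.g. because a remote substituent atom was added --
#' never moves existing nodes.
#'
#' @param ligand A [molecule_pose()].
#' @param spacing Grid spacing in Angstrom (default 0.1, i.e. 1000 points
#'   per cubic Angstrom).
#' @param margin Box margin in Angstrom beyond the ligand bounding box
#'   (default 3.0; overlap regions extend roughly 4 A of summed distance).
#' @return An object of class `grid_spec`: list with `origin` (A),
#'   `spacing` (A), `shape` (3 integers).
#' @export
make_grid <- function(ligand, spacing = 0.1, margin = 3.0) {
  if (spacing <= 0) .stopf("spacing must be positive")
  if (margin < 0) .stopf("margin must be non-negative")
  if (nrow(ligand) == 0L) .stopf("empty ligand pose")
  xyz <- pose_xyz(ligand)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  i0 <- floor(lo / spacing + 1e-9)
  i1 <- ceiling(hi / spacing - 1e-9)
  structure(
    list(origin = i0 * spacing, spacing = spacing,
         shape = as.integer(i1 - i0 + 1)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d nodes at %g A, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid node coordinates and indices
#'
#' Nodes are ordered lexicographically by integer index `(ix, iy, iz)`
#' with `iz` varying fastest; this ordering is the package-wide output
#' convention (and the Gaussian-cube value order).
#'
#' @param grid A `grid_spec`.
#' @return Data frame with columns `ix`, `iy`, `iz` (0-based indices) and
#'   `x`, `y`, `z` (Angstrom).
#' @export
grid_points <- function(grid) {
  s <- grid$shape
  idx <- expand.grid(iz = seq_len(s[3]) - 1L, iy = seq_len(s[2]) - 1L,
                     ix = seq_len(s[1]) - 1L)
  data.frame(ix = idx$ix, iy = idx$iy, iz = idx$iz,
             x = grid$origin[1] + idx$ix * grid$spacing,
             y = grid$origin[2] + idx$iy * grid$spacing,
             z = grid$origin[3] + idx$iz * grid$spacing)
}

## the normalisation term; isolated here so an alternative algebraic form
## can be swapped in one place
.rho_n <- function(NL, NE, rhoLC, rhoEC) log(NL * NE) - log(rhoLC * rhoEC)

#' Overlap points between ligand and receptor electron clouds
#'
#' Evaluates both promolecular densities on the grid and keeps the points
#' where both reach the model's `rho_min`. For every kept point the
#' highest-contributing atom of each molecule, the distance sum SUMDLE,
#' the normalisation term rhoN, the per-molecule contributors
#' sigma_ligand/sigma_enzyme, and the regressand
#' `y_value = ln(rho_ligand * rho_enzyme) + rhoN` are recorded.
#'
#' @param model A [density_model()].
#' @param receptor,ligand [molecule_pose()] objects in a common frame.
#' @param grid Optional `grid_spec`; defaults to
#'   `make_grid(ligand, 0.1, 3.0)`.
#' @param chunk Number of grid nodes processed per block (memory control).
#' @return A data frame of class `overlap_points`, ordered by grid index,
#'   with columns `ix iy iz x y z rho_ligand rho_enzyme lig_index enz_index
#'   lig_serial enz_serial dist_ligand dist_enzyme sumdle rho_n
#'   sigma_ligand sigma_enzyme y_value`. Attributes carry the grid and the
#'   pose labels.
#' @export
overlap_points <- function(model, receptor, ligand, grid = NULL,
                           chunk = 200000L) {
  if (nrow(receptor) == 0L || nrow(ligand) == 0L)
    .stopf("receptor and ligand must be non-empty")
  if (is.null(grid)) grid <- make_grid(ligand)
  gp <- grid_points(grid)
  ## pass 1: ligand density (few atoms), keep candidate nodes
  keep_list <- list()
  n <- nrow(gp)
  starts <- seq(1L, n, by = chunk)
  for (s0 in starts) {
    rows <- s0:min(s0 + chunk - 1L, n)
    dl <- molecular_density(model, ligand,
                            as.matrix(gp[rows, c("x", "y", "z")]))
    ok <- dl$rho_total >= model$rho_min
    if (any(ok)) {
      blk <- gp[rows[ok], , drop = FALSE]
      blk$rho_ligand <- dl$rho_total[ok]
      blk$lig_index <- dl$top_index[ok]
      blk$dist_ligand <- dl$top_distance[ok]
      keep_list[[length(keep_list) + 1L]] <- blk
    }
  }
  pts <- do.call(rbind, keep_list)
  if (is.null(pts) || nrow(pts) == 0L)
    .stopf("no overlap points: the ligand density never reaches rho_min on the grid")
  ## pass 2: receptor density at the surviving nodes only
  de <- molecular_density(model, receptor,
                          as.matrix(pts[, c("x", "y", "z")]))
  ok <- de$rho_total >= model$rho_min
  if (!any(ok))
    .stopf("no overlap points: ligand and receptor clouds do not touch at rho_min = %g e/A^3",
           model$rho_min)
  pts <- pts[ok, , drop = FALSE]
  pts$rho_enzyme <- de$rho_total[ok]
  pts$enz_index <- de$top_index[ok]
  pts$dist_enzyme <- de$top_distance[ok]

  pts$lig_serial <- ligand$serial[pts$lig_index]
  pts$enz_serial <- receptor$serial[pts$enz_index]
  NL <- ligand$atomic_number[pts$lig_index]
  NE <- receptor$atomic_number[pts$enz_index]
  rhoLC <- .center_densities(model, ligand, pts$lig_index)
  rhoEC <- .center_densities(model, receptor, pts$enz_index)

  pts$sumdle <- pts$dist_ligand + pts$dist_enzyme
  pts$rho_n <- .rho_n(NL, NE, rhoLC, rhoEC)
  pts$sigma_ligand <- log(pts$rho_ligand * NL / rhoLC)
  pts$sigma_enzyme <- log(pts$rho_enzyme * NE / rhoEC)
  pts$y_value <- log(pts$rho_ligand * pts$rho_enzyme) + pts$rho_n

  cols <- c("ix", "iy", "iz", "x", "y", "z", "rho_ligand", "rho_enzyme",
            "lig_index", "enz_index", "lig_serial", "enz_serial",
            "dist_ligand", "dist_enzyme", "sumdle", "rho_n",
            "sigma_ligand", "sigma_enzyme", "y_value")
  pts <- pts[order(pts$ix, pts$iy, pts$iz), cols]
  rownames(pts) <- NULL
  attr(pts, "grid") <- grid
  attr(pts, "receptor_label") <- pose_label(receptor)
  attr(pts, "ligand_label") <- pose_label(ligand)
  attr(pts, "rho_min") <- model$rho_min
  class(pts) <- c("overlap_points", "data.frame")
  pts
}

#' Fit the complementarity line
#'
#' Ordinary least squares of the regressand on SUMDLE over the overlap
#' points. The slope `a` (A^-1) reflects binding efficiency (more negative
#' = steeper, tighter complementarity); the intercept `b` is dimensionless.
#'
#' @param points An `overlap_points` data frame (or any data frame with
#'   `sumdle` and `y_value` columns).
#' @param label Optional label stored in the result (defaults to the
#'   ligand label of `points`).
#' @return An object of class `complementarity_fit`: list with `a`, `b`,
#'   `r2`, `adj_r2` (`= 1 - (1 - r2)(n-1)/(n-2)`), `n_points`,
#'   `residual_sd`, `label`.
#' @export
fit_complementarity <- function(points, label = NULL) {
  n <- nrow(points)
  if (n < 3L) .stopf("need at least 3 overlap points to fit, got %d", n)
  if (length(unique(points$sumdle)) < 2L)
    .stopf("singular fit: all SUMDLE values are identical")
  fit <- stats::lm(y_value ~ sumdle, data = points)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((points$y_value - mean(points$y_value))^2)
  r2 <- 1 - rss / tss
  structure(
    list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
         r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
         n_points = n, residual_sd = sqrt(rss / (n - 2)),
         label = label %||% attr(points, "ligand_label") %||% "fit"),
    class = "complementarity_fit")
}

#' @export
print.complementarity_fit <- function(x, ...) {
  cat(sprintf(
    "complementarity_fit '%s': a = %.4f A^-1, b = %.4f, R2 = %.4f (adj %.4f), n = %d\n",
    x$label, x$a, x$b, x$r2, x$adj_r2, x$n_points))
  invisible(x)
}

#' Export overlap points as TSV
#'
#' Deterministic fixed-format (6 significant digits) export; includes the
#' cluster assignment column when present.
#'
#' @param points An `overlap_points` data frame (optionally carrying a
#'   `cluster_id` column from [cluster_contacts()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_points_tsv <- function(points, path) {
  cid <- if ("cluster_id" %in% names(points)) points$cluster_id else NA_integer_
  out <- data.frame(
    x = .fmt_num(points$x), y = .fmt_num(points$y), z = .fmt_num(points$z),
    rho_ligand = .fmt_num(points$rho_ligand),
    rho_enzyme = .fmt_num(points$rho_enzyme),
    lig_atom_serial = points$lig_serial, enz_atom_serial = points$enz_serial,
    dist_ligand = .fmt_num(points$dist_ligand),
    dist_enzyme = .fmt_num(points$dist_enzyme),
    sumdle = .fmt_num(points$sumdle), rho_n = .fmt_num(points$rho_n),
    y_value = .fmt_num(points$y_value), cluster_id = cid)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a fit as JSON
#'
#' @param fit A `complementarity_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(label = fit$label, a = fit$a, b = fit$b, r2 = fit$r2,
         adj_r2 = fit$adj_r2, n_points = fit$n_points),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Write a molecular density grid as a Gaussian cube file
#'
#' @param model A [density_model()].
#' @param pose The molecule whose density is exported.
#' @param grid A `grid_spec`.
#' @param path Output file path.
#' @param comment Header comment line.
#' @return `path`, invisibly.
#' @export
write_cube <- function(model, pose, grid, path,
                       comment = "promolecular Slater-type density") {
  gp <- grid_points(grid)
  rho <- molecular_density(model, pose, as.matrix(gp[, c("x", "y", "z")]))
  vals <- rho$rho_total * BOHR_A^3    # e/A^3 -> e/bohr^3
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "denscomp cube export (values in e/bohr^3)"), con)
  o <- grid$origin / BOHR_A
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", nrow(pose), o[1], o[2], o[3]), con)
  st <- grid$spacing / BOHR_A
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$shape[1], st, 0, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$shape[2], 0, st, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", grid$shape[3], 0, 0, st), con)
  xyz_b <- pose_xyz(pose) / BOHR_A
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", pose$atomic_number,
                     as.numeric(pose$atomic_number),
                     xyz_b[, 1], xyz_b[, 2], xyz_b[, 3]), con)
  ## cube value order: x slowest, z fastest -- grid_points() order
  lines <- tapply(sprintf("%13.5E", vals),
                  (seq_along(vals) - 1L) %/% 6L, paste, collapse = "")
  writeLines(unname(lines), con)
  invisible(path)
}
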