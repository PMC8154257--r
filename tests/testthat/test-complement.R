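test_that("grid shapes enumerate lattice points of the padded bounding box", {
  one <- molecule_pose("C", matrix(0, 1, 3), label = "one")
  expect_equal(make_grid(one, spacing = 0.1, margin = 0.5)$shape,
               c(11L, 11L, 11L))
  expect_equal(make_grid(one, spacing = 0.1, margin = 0)$shape, c(1L, 1L, 1L))
  two <- molecule_pose(c("C", "C"), rbind(c(0, 0, 0), c(1, 2, 3)),
                       label = "two")
  expect_equal(make_grid(two, spacing = 0.5, margin = 1)$shape,
               c(7L, 9L, 11L))
  expect_error(make_grid(one, spacing = 0), "positive")
})

test_that("grid nodes sit on the absolute lattice, ordered lexicographically", {
  pose <- molecule_pose("C", matrix(c(0.73, -0.21, 1.9), 1), label = "p")
  g <- make_grid(pose, spacing = 0.1, margin = 1)
  gp <- grid_points(g)
  expect_equal(nrow(gp), prod(g$shape))
  ## every node is an integer multiple of the spacing
  expect_true(all(abs(gp$x / 0.1 - round(gp$x / 0.1)) < 1e-9))
  ## lexicographic (ix, iy, iz) ordering
  expect_true(!is.unsorted(order(gp$ix, gp$iy, gp$iz)))
  expect_equal(gp[order(gp$ix, gp$iy, gp$iz), ], gp)
})

test_that("overlap points obey the closed-form single-exponential algebra", {
  pair <- make_single_zeta_pair(zeta = 1, Z = 1, separation = 3)
  pts <- overlap_points(pair$model, pair$receptor, pair$ligand)
  ## y = -2 zeta SUMDLE exactly (b = ln(1*1) = 0), zeta converted to A^-1
  expect_lt(max(abs(pts$y_value - (-2 / bohr_radius()) * pts$sumdle)), 1e-9)
  ## the sigma decomposition is an identity at every point
  expect_lt(max(abs(pts$y_value - (pts$sigma_ligand + pts$sigma_enzyme))),
            1e-10)
  expect_equal(pts$sumdle, pts$dist_ligand + pts$dist_enzyme)
  ## midline points have equal distances by symmetry
  mid <- pts[abs(pts$x - 1.5) < 1e-9, ]
  expect_gt(nrow(mid), 0)
  expect_equal(mid$dist_ligand, mid$dist_enzyme, tolerance = 1e-12)
})

test_that("disjoint clouds raise a no-overlap error", {
  pair <- make_single_zeta_pair(separation = 60)
  expect_error(overlap_points(pair$model, pair$receptor, pair$ligand),
               "no overlap")
})

test_that("fit recovers an exact line and matches the normal-equations oracle", {
  ## points on y = 6.52 - 4.03 x recovered to machine precision
  x <- seq(2, 6, by = 0.25)
  exact <- data.frame(sumdle = x, y_value = 6.52 - 4.03 * x)
  fit <- fit_complementarity(exact)
  expect_equal(fit$a, -4.03, tolerance = 1e-12)
  expect_equal(fit$b, 6.52, tolerance = 1e-12)
  expect_gt(fit$r2, 1 - 1e-12)
  ## OLS on noisy data equals the closed-form solution
  set.seed(3)
  noisy <- data.frame(sumdle = runif(20, 2, 8))
  noisy$y_value <- 5 - 4 * noisy$sumdle + rnorm(20, 0, 0.3)
  fit2 <- fit_complementarity(noisy)
  ref <- oracle_ols(noisy$sumdle, noisy$y_value)
  expect_equal(fit2$b, ref[1], tolerance = 1e-10)
  expect_equal(fit2$a, ref[2], tolerance = 1e-10)
  ## adjusted R2 definition
  expect_equal(fit2$adj_r2,
               1 - (1 - fit2$r2) * (20 - 1) / (20 - 2), tolerance = 1e-12)
})

test_that("degenerate regressions are rejected", {
  expect_error(fit_complementarity(data.frame(sumdle = c(1, 2),
                                              y_value = c(1, 2))),
               "at least 3")
  expect_error(fit_complementarity(data.frame(sumdle = rep(2, 5),
                                              y_value = rnorm(5))),
               "identical")
})

test_that("the single-exponent fit is exact for any geometry", {
  ## softer/heavier pseudo-atoms keep the clouds overlapping out to 5 A
  for (sep in c(2, 3, 5)) {
    pair <- make_single_zeta_pair(zeta = 0.8, Z = 6, separation = sep)
    fit <- fit_complementarity(overlap_points(pair$model, pair$receptor,
                                              pair$ligand))
    expect_equal(fit$a, pair$expected$a, tolerance = 1e-6)
    expect_equal(fit$b, pair$expected$b, tolerance = 1e-6)
    expect_lt(fit$residual_sd, 1e-8)
  }
})

test_that("rigid-body motion changes the fit only within grid tolerance", {
  model <- density_model()
  rec <- molecule_pose(c("C", "C"), rbind(c(0, 0, 0), c(2.5, 0, 0)),
                       resname = "REC", is_hetero = FALSE, label = "rec")
  lig <- molecule_pose("N", matrix(c(1.25, 3.0, 0), 1), label = "lig")
  f1 <- fit_complementarity(overlap_points(model, rec, lig))
  theta <- 0.9
  R <- rbind(c(cos(theta), 0, sin(theta)), c(0, 1, 0),
             c(-sin(theta), 0, cos(theta)))
  shift <- c(3.3, -1.7, 0.45)
  move <- function(p, lab) molecule_pose(
    p$element, sweep(pose_xyz(p) %*% t(R), 2, shift, "+"),
    resname = p$resname, is_hetero = p$is_hetero, label = lab)
  f2 <- fit_complementarity(overlap_points(model, move(rec, "rec2"),
                                           move(lig, "lig2")))
  expect_lt(abs(f1$a - f2$a), 0.01)
  expect_lt(abs(f1$b - f2$b), 0.05)
})

test_that("a remote substituent atom leaves the fit untouched", {
  pair <- make_single_zeta_pair(zeta = 1, Z = 1, separation = 3)
  f1 <- fit_complementarity(overlap_points(pair$model, pair$receptor,
                                           pair$ligand))
  lig2 <- molecule_pose(c("Q", "Q"), rbind(c(3, 0, 0), c(28, 0, 0)),
                        extra_elements = c(Q = 1L), label = "lig_far")
  f2 <- fit_complementarity(overlap_points(pair$model, pair$receptor, lig2))
  expect_lt(abs(f1$a - f2$a), 1e-6)
  expect_lt(abs(f1$b - f2$b), 1e-6)
  expect_equal(f1$n_points, f2$n_points)
})

test_that("lowering rho_min only appends weaker, larger-SUMDLE points", {
  mk_model <- function(rm) density_model(
    extra_shells = data.frame(element = "Q", n = 1L, zeta = 1, occupancy = 1),
    extra_elements = c(Q = 1L), rho_min = rm)
  pair <- make_single_zeta_pair(zeta = 1, Z = 1, separation = 3)
  hi <- overlap_points(mk_model(0.002), pair$receptor, pair$ligand)
  lo <- overlap_points(mk_model(0.001), pair$receptor, pair$ligand)
  key <- function(p) paste(p$ix, p$iy, p$iz)
  expect_true(all(key(hi) %in% key(lo)))
  extra <- lo[!(key(lo) %in% key(hi)), ]
  expect_gt(nrow(extra), 0)
  expect_gte(min(extra$sumdle), min(hi$sumdle))
  expect_gte(max(extra$sumdle), max(hi$sumdle))
})

test_that("points TSV and fit JSON exports are written and re-readable", {
  pair <- make_single_zeta_pair()
  pts <- overlap_points(pair$model, pair$receptor, pair$ligand)
  fit <- fit_complementarity(pts)
  tsv <- tempfile(fileext = ".tsv")
  write_points_tsv(pts, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(pts))
  expect_equal(back$sumdle, as.numeric(.fmt <- sprintf("%.6g", pts$sumdle)))
  js <- tempfile(fileext = ".json")
  write_fit_json(fit, js)
  got <- jsonlite::read_json(js)
  expect_equal(got$a, fit$a, tolerance = 1e-9)
  expect_equal(got$n_points, nrow(pts))
})

test_that("cube export round-trips the density grid values", {
  pair <- make_single_zeta_pair()
  grid <- make_grid(pair$ligand, spacing = 0.5, margin = 1)
  path <- tempfile(fileext = ".cube")
  write_cube(pair$model, pair$ligand, grid, path)
  lines <- readLines(path)
  expect_equal(length(lines), 6 + 1 + ceiling(prod(grid$shape) / 6))
  vals <- as.numeric(unlist(lapply(lines[-(1:7)], function(l)
    substring(l, seq(1, nchar(l), 13), seq(13, nchar(l), 13)))))
  gp <- grid_points(grid)
  ref <- molecular_density(pair$model, pair$ligand,
                           as.matrix(gp[, c("x", "y", "z")]))$rho_total
  expect_equal(vals, ref * bohr_radius()^3, tolerance = 1e-4)
})
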