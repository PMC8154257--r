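## hydrogen-like single-shell model used in several closed-form checks
single_shell_model <- function(zeta = 1, Z = 1L, symbol = "Q") {
  density_model(
    extra_shells = data.frame(element = symbol, n = 1L, zeta = zeta,
                              occupancy = Z),
    extra_elements = stats::setNames(as.integer(Z), symbol))
}

test_that("1s density at the nucleus equals zeta^3/pi (unit-converted)", {
  model <- single_shell_model(zeta = 1)
  a0 <- bohr_radius()
  expect_equal(atomic_density(model, "Q", 0), (1 / pi) / a0^3,
               tolerance = 1e-12)
  ## and for a non-unit exponent
  model2 <- single_shell_model(zeta = 1.7)
  expect_equal(atomic_density(model2, "Q", 0), (1.7^3 / pi) / a0^3,
               tolerance = 1e-12)
})

test_that("density decays to numerical zero far away and is positive before", {
  model <- density_model()
  for (el in c("H", "C", "S")) {
    expect_lt(atomic_density(model, el, 50), 1e-12)
    expect_true(all(atomic_density(model, el, seq(0, 12, by = 0.5)) > 0))
  }
})

test_that("radially integrated density equals the atomic number per element", {
  model <- density_model()
  for (el in names(model$shells)) {
    z <- atomic_number(el)
    integrand <- function(r) 4 * pi * r^2 * atomic_density(model, el, r)
    ## split at 1 A: heavy-element cores are sharp
    q <- stats::integrate(integrand, 0, 1, rel.tol = 1e-9,
                          subdivisions = 500L)$value +
      stats::integrate(integrand, 1, 60, rel.tol = 1e-9,
                       subdivisions = 500L)$value
    expect_equal(q, z, tolerance = 1e-3 * z)
  }
})

test_that("atomic density decays monotonically beyond its outermost maximum", {
  model <- density_model()
  r <- seq(0.02, 12, by = 0.02)
  for (el in names(model$shells)) {
    rho <- atomic_density(model, el, r)
    d <- diff(rho)
    last_rise <- if (any(d > 0)) max(which(d > 0)) else 0L
    expect_true(all(d[seq(last_rise + 1L, length(d))] <= 0), label = el)
    ## outermost maximum sits within bonding range even for alkali shells
    expect_lt(r[last_rise + 1L], 3)
  }
})

test_that("molecular density matches a cutoff-free brute-force sum", {
  model <- density_model()
  set.seed(7)
  pose <- molecule_pose(c("C", "N", "O"), matrix(runif(9, 0, 3), 3),
                        label = "toy")
  pts <- matrix(runif(15, -1, 4), ncol = 3)
  got <- molecular_density(model, pose, pts)
  brute <- sapply(seq_len(nrow(pts)), function(m) {
    sum(sapply(seq_len(3), function(i) {
      d <- sqrt(sum((pts[m, ] - c(pose$x[i], pose$y[i], pose$z[i]))^2))
      atomic_density(model, pose$element[i], d)
    }))
  })
  expect_equal(got$rho_total, brute, tolerance = 1e-9)
})

test_that("top-contributor ties break to the lower serial", {
  model <- single_shell_model()
  pose <- molecule_pose(c("Q", "Q"),
                        rbind(c(0, 0, 0), c(2, 0, 0)),
                        extra_elements = c(Q = 1L), label = "sym")
  res <- molecular_density(model, pose, c(1, 0, 0))
  expect_equal(res$top_serial, 1L)
  expect_equal(res$rho_total, 2 * atomic_density(model, "Q", 1),
               tolerance = 1e-12)
  expect_equal(res$top_distance, 1)
})

test_that("single-atom pose: point at the center reproduces the center density", {
  model <- single_shell_model(zeta = 1.3)
  pose <- molecule_pose("Q", matrix(c(1, 2, 3), 1),
                        extra_elements = c(Q = 1L), label = "one")
  res <- molecular_density(model, pose, c(1, 2, 3))
  expect_equal(res$top_distance, 0)
  expect_equal(res$rho_total, atomic_density(model, "Q", 0))
})

test_that("center density includes neighbour tails (two-term closed form)", {
  model <- single_shell_model(zeta = 1)
  pose <- molecule_pose(c("Q", "Q"), rbind(c(0, 0, 0), c(1, 0, 0)),
                        extra_elements = c(Q = 1L), label = "two")
  expected <- atomic_density(model, "Q", 0) + atomic_density(model, "Q", 1)
  expect_equal(center_density(model, pose, 1), expected, tolerance = 1e-12)
  ## always at least the atom's own r = 0 contribution
  expect_gte(center_density(model, pose, 1), atomic_density(model, "Q", 0))
  ## isolated mode drops the tails
  model_iso <- density_model(
    extra_shells = data.frame(element = "Q", n = 1L, zeta = 1, occupancy = 1),
    extra_elements = c(Q = 1L), center_mode = "isolated")
  expect_equal(center_density(model_iso, pose, 1),
               atomic_density(model, "Q", 0))
  expect_error(center_density(model, pose, 99), "not in pose")
})

test_that("densities are equivariant under rigid motion", {
  model <- density_model()
  set.seed(11)
  pose <- molecule_pose(c("C", "O", "N", "H"), matrix(runif(12, 0, 3), 4),
                        label = "eq")
  pts <- matrix(runif(9, -1, 4), ncol = 3)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  shift <- c(5, -3, 2)
  pose2 <- molecule_pose(pose$element,
                         sweep(pose_xyz(pose) %*% t(R), 2, shift, "+"),
                         label = "eq2")
  pts2 <- sweep(pts %*% t(R), 2, shift, "+")
  expect_equal(molecular_density(model, pose2, pts2)$rho_total,
               molecular_density(model, pose, pts)$rho_total,
               tolerance = 1e-10)
})

test_that("hydrogen handling and shell-table validation behave as configured", {
  model_noh <- density_model(include_hydrogens = FALSE)
  pose <- molecule_pose(c("C", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
                        label = "ch")
  res <- molecular_density(model_noh, pose, c(0.5, 0, 0))
  expect_equal(res$rho_total,
               atomic_density(model_noh, "C", 0.5), tolerance = 1e-12)
  expect_error(atomic_density(density_model(), "Zz", 1),
               "no density parameters")
  ## occupancies must sum to the atomic number
  expect_error(density_model(
    extra_shells = data.frame(element = "Q", n = 1, zeta = 1, occupancy = 2),
    extra_elements = c(Q = 1L)), "sum to")
})
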