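test_that("a point-free window carries the bare bulk current", {
  empty <- point_free_structure()
  vp <- velocity_profile(r_o = 3, R = 35)
  rd <- load_ramachandran(250)
  d <- sample_currents(empty, c("K+" = 5, "Cl-" = 5), rd, vp, n = 50,
                       seed = 1, z_margin = Inf, grid_step = 0.05)
  expect_true(isTRUE(d$point_mass))
  # I = 2 q g_bulk v_bulk A with A = pi (17.5 A)^2: about 71.7 nA/species
  analytic <- 2 * 1.602176634e-19 * 6.02214076e26 * 77.23 *
    (pi * 17.5^2 * 1e-20) * 1e9
  expect_equal(d$at, analytic, tolerance = 0.005)
  expect_gt(analytic, 140)  # the tens-of-nA regime
  expect_lt(analytic, 150)
})

test_that("azimuthal symmetry gives zero current variance", {
  sph <- make_spheres(c(0, 0, 0), 2.5)
  vp <- velocity_profile(r_o = 2.5, R = 35)
  rd <- load_ramachandran(250)
  d <- sample_currents(sph, c("K+" = 4, "Cl-" = 3), rd, vp, n = 100,
                       seed = 3, grid_step = 0.1)
  expect_true(isTRUE(d$point_mass))
})

test_that("sampling is deterministic given the seed", {
  s <- load_residue_template("ALA")
  vp <- velocity_profile(mean_surface_radius(s, 1e4))
  rd <- load_ramachandran(250)
  d1 <- sample_currents(s, c("K+" = 5, "Cl-" = 4), rd, vp, n = 200,
                        seed = 42, grid_step = 0.1)
  d2 <- sample_currents(s, c("K+" = 5, "Cl-" = 4), rd, vp, n = 200,
                        seed = 42, grid_step = 0.1)
  expect_identical(d1$samples, d2$samples)
  d3 <- sample_currents(s, c("K+" = 5, "Cl-" = 4), rd, vp, n = 200,
                        seed = 43, grid_step = 0.1)
  expect_false(identical(d1$samples, d3$samples))
})

test_that("currents shrink as the effective radii grow", {
  s <- load_residue_template("LEU")
  vp <- velocity_profile(mean_surface_radius(s, 1e4))
  rd <- load_ramachandran(250)
  means <- vapply(c(2, 4, 6), function(re) {
    d <- sample_currents(s, c("K+" = re, "Cl-" = re), rd, vp, n = 300,
                         seed = 7, grid_step = 0.1)
    mean(d$samples)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("MC areas agree with the single-conformation area measurement", {
  s <- load_residue_template("GLN")
  vp <- velocity_profile(mean_surface_radius(s, 1e4))
  reff <- c("K+" = 6.1, "Cl-" = 6.1)
  set.seed(9)
  for (k in 1:3) {
    conf <- conformation(phi = runif(1, -180, 180),
                         psi = runif(1, -180, 180),
                         azimuth = runif(1, 0, 360))
    i_mc <- ionseqsim:::.currents_for_conformations(
      s, reff, vp, conf$phi, conf$psi, conf$azimuth, grid_step = 0.05)
    rot <- apply_conformation(s, conf)
    a <- plane_exclusion_area(rot, 6.1, vp$R / 2, z_margin = 1.9)
    i_direct <- 2 * ionseqsim:::.current_nA(a, 1.0, vp$v_bulk)
    expect_equal(i_mc, i_direct, tolerance = 1e-9)
  }
})

test_that("histogram + spline distributions behave like densities", {
  set.seed(21)
  u <- runif(1e5, 10, 20)
  d <- build_distribution(u, n_bins = 25)
  xs <- d$mids[d$mids > 11 & d$mids < 19]
  expect_true(all(abs(dist_density(d, xs) - 0.1) < 0.005))
  fine <- seq(11, 19, by = 0.05)
  expect_lt(mean(abs(dist_density(d, fine) - 0.1)), 0.0025)
  # normalization over the support
  grid <- seq(d$support[1], d$support[2], length.out = 20001)
  pdf <- dist_density(d, grid)
  expect_equal(sum((pdf[-1] + pdf[-length(pdf)]) / 2 * diff(grid)), 1,
               tolerance = 1e-6)
  expect_equal(sum(d$masses), 1, tolerance = 1e-12)
  expect_identical(dist_density(d, c(5, 25)), c(0, 0))

  # two separated clusters give a bimodal spline PDF
  set.seed(22)
  bi <- c(rnorm(5000, 5, 0.3), rnorm(5000, 15, 0.3))
  db <- build_distribution(bi, n_bins = 80)
  xg <- seq(db$support[1], db$support[2], length.out = 2000)
  dens <- dist_density(db, xg)
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  peaks <- peaks[dens[peaks] > 0.1]
  expect_gte(length(peaks), 2)

  expect_error(build_distribution(rep(7, 10)), "identical")
})

test_that("azimuthally asymmetric shapes pile mass at the current extremes", {
  shape <- make_spheres(rbind(c(2.5, 0, 0), c(-2.5, 0, 0), c(0, 0, 0)),
                        c(1.8, 1.8, 1.8))
  vp <- velocity_profile(r_o = 4.3, R = 35)
  rd <- load_ramachandran(250)
  d <- sample_currents(shape, c("K+" = 4, "Cl-" = 4), rd, vp, n = 4000,
                       seed = 5, grid_step = 0.1, n_bins = 40)
  m <- d$masses
  expect_gt(max(m[1], m[length(m)]), stats::median(m))
})

test_that("the mean current is stable when the sample count doubles", {
  s <- load_residue_template("GLY")
  vp <- velocity_profile(mean_surface_radius(s, 1e4))
  rd <- load_ramachandran(250)
  reff <- c("K+" = 6.6, "Cl-" = 6.6)
  d1 <- sample_currents(s, reff, rd, vp, n = 5e4, seed = 31, grid_step = 0.1)
  d2 <- sample_currents(s, reff, rd, vp, n = 1e5, seed = 32, grid_step = 0.1)
  expect_lt(abs(mean(d1$samples) - mean(d2$samples)) / mean(d2$samples),
            0.01)
})
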