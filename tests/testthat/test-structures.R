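test_that("residue templates load with expected atom contents", {
  gly <- load_residue_template("GLY")
  counts <- vapply(residue_codes(), function(r) {
    nrow(load_residue_template(r)$atoms)
  }, numeric(1))
  expect_equal(unname(which.min(counts)), match("GLY", residue_codes()))
  expect_gt(counts[["TRP"]], counts[["GLY"]])
  expect_error(load_residue_template("XXX"), "unknown residue")
  # centered: backbone centroid on the z axis
  for (r in c("GLY", "LYS", "TRP")) {
    s <- load_residue_template(r)
    bb <- s$atoms[s$backbone, ]
    expect_lt(abs(mean(bb$x)), 1e-3)
    expect_lt(abs(mean(bb$y)), 1e-3)
    expect_true(all(s$atoms$vdw > 0))
  }
})

test_that("conformation rotations are rigid and compose correctly", {
  s <- load_residue_template("LYS")
  p0 <- as.matrix(s$atoms[, c("x", "y", "z")])

  ident <- apply_conformation(s, conformation(180, 180, 0))
  expect_equal(as.matrix(ident$atoms[, c("x", "y", "z")]), p0,
               tolerance = 1e-12)

  full <- apply_conformation(s, conformation(180, 180, 360))
  expect_equal(as.matrix(full$atoms[, c("x", "y", "z")]), p0,
               tolerance = 1e-9)

  twice <- apply_conformation(apply_conformation(s, conformation(180, 180, 90)),
                              conformation(180, 180, 90))
  once <- apply_conformation(s, conformation(180, 180, 180))
  expect_equal(as.matrix(twice$atoms[, c("x", "y", "z")]),
               as.matrix(once$atoms[, c("x", "y", "z")]), tolerance = 1e-9)

  # all pairwise distances within each rigid body are preserved under
  # arbitrary dihedrals + azimuth
  conf <- conformation(phi = -151, psi = 153, azimuth = 37)
  rot <- apply_conformation(s, conf)
  p1 <- as.matrix(rot$atoms[, c("x", "y", "z")])
  part <- ionseqsim:::.dihedral_partition(s)
  for (grp in 0:2) {
    idx <- which(part == grp)
    if (length(idx) >= 2) {
      expect_equal(as.numeric(dist(p1[idx, ])), as.numeric(dist(p0[idx, ])),
                   tolerance = 1e-9)
    }
  }
  # bonds crossing a partition boundary keep their lengths too (rotation
  # axes pass through the shared backbone atoms)
  iN <- s$backbone[1]; iH <- which(s$atoms$name == "H")[1]
  expect_equal(sqrt(sum((p1[iN, ] - p1[iH, ])^2)),
               sqrt(sum((p0[iN, ] - p0[iH, ])^2)), tolerance = 1e-9)
})

test_that("mean surface radius matches sphere and quadrature oracles", {
  one <- make_spheres(c(0, 0, 0), 1.7)
  expect_equal(mean_surface_radius(one, 1e4), 1.7, tolerance = 1e-9)

  a <- 1.5; c0 <- 1.0
  two <- make_spheres(rbind(c(0, 0, -c0), c(0, 0, c0)), c(a, a))
  oracle <- two_sphere_mean_radius_oracle(a, c0)
  expect_equal(mean_surface_radius(two, 1e5), oracle, tolerance = 1e-3)

  # upper bound and azimuthal invariance on a real residue
  s <- load_residue_template("TRP")
  r_o <- mean_surface_radius(s, 1e5)
  bound <- max(sqrt(rowSums(as.matrix(s$atoms[, c("x", "y", "z")])^2)) +
               s$atoms$vdw)
  expect_lte(r_o, bound)
  rot <- apply_conformation(s, conformation(180, 180, 133))
  expect_equal(mean_surface_radius(rot, 1e5), r_o, tolerance = 1e-3)

  off <- make_spheres(c(10, 0, 0), 1.0)
  expect_error(mean_surface_radius(off), "outside")
})

test_that("shell volumes agree with analytic and Monte Carlo oracles", {
  sph <- make_spheres(c(0, 0, 0), 2)
  v <- shell_volume(sph, 0, 0.5, grid_step = 0.05)
  expect_equal(v, 4 * pi / 3 * (2.5^3 - 2^3), tolerance = 0.02)

  expect_equal(shell_volume(sph, 1, 1, grid_step = 0.1), 0)

  two <- make_spheres(rbind(c(0, 0, -1), c(0, 0, 1)), c(1.5, 1.5))
  v2 <- shell_volume(two, 0, 1, grid_step = 0.1)
  expect_equal(v2, mc_shell_volume_oracle(two, 0, 1, n = 1e7),
               tolerance = 0.02)

  # additivity over contiguous shells
  va <- shell_volume(two, 0, 0.5, grid_step = 0.1)
  vb <- shell_volume(two, 0.5, 1, grid_step = 0.1)
  expect_equal(va + vb, v2, tolerance = 1e-9)

  # first-order grid convergence: halving the step shrinks the change
  v_2 <- shell_volume(sph, 0, 0.5, grid_step = 0.2)
  v_1 <- shell_volume(sph, 0, 0.5, grid_step = 0.1)
  v_05 <- shell_volume(sph, 0, 0.5, grid_step = 0.05)
  expect_lt(abs(v_05 - v_1), abs(v_1 - v_2))
})

test_that("plane exclusion area matches analytic disks and the MC oracle", {
  empty <- point_free_structure()
  a_disk <- plane_exclusion_area(empty, 0, 17.5, z_margin = Inf)
  expect_equal(a_disk, pi * 17.5^2, tolerance = 0.005)

  one <- make_spheres(c(0, 0, 0), 1.7)
  a_ann <- plane_exclusion_area(one, 1.3, 17.5, z_margin = Inf)
  expect_equal(a_ann, pi * 17.5^2 - pi * 3^2, tolerance = 0.005)

  lys <- load_residue_template("LYS")
  zw <- lys$terminal_z_extent + 1.9
  a_pkg <- plane_exclusion_area(lys, 5.38, 17.5, z_margin = 1.9)
  a_mc <- mc_plane_area_oracle(lys, 5.38, 17.5, zw, n = 1e7)
  expect_equal(a_pkg, a_mc, tolerance = 0.01)

  # monotone non-increasing in the inflation radius
  infl <- c(0, 1, 2.5, 4, 5.38, 7)
  areas <- vapply(infl, function(ri) {
    plane_exclusion_area(lys, ri, 17.5, grid_step = 0.1)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))

  # grid convergence
  a2 <- plane_exclusion_area(one, 1.3, 17.5, z_margin = Inf, grid_step = 0.2)
  a1 <- plane_exclusion_area(one, 1.3, 17.5, z_margin = Inf, grid_step = 0.1)
  a05 <- plane_exclusion_area(one, 1.3, 17.5, z_margin = Inf, grid_step = 0.05)
  expect_lt(abs(a05 - a1), abs(a1 - a2) + 1e-9)
})
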