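test_that("computed pRDFs recover known shell concentrations", {
  sph <- make_spheres(c(0, 0, 0), 2)

  # all-empty frames give zero concentration everywhere
  p0 <- compute_prdf(list(matrix(numeric(0), ncol = 3),
                          matrix(numeric(0), ncol = 3)),
                     sph, "K+", r_max = 4)
  expect_true(all(p0$g == 0))

  # one ion at 0.25 A from the surface lands in the first shell only
  p1 <- compute_prdf(list(matrix(c(2.25, 0, 0), ncol = 3)), sph, "K+",
                     r_max = 4)
  v1 <- shell_volume(sph, 0, 0.5, grid_step = 0.1)
  expect_equal(p1$g[1], 1 / v1 / 6.02214076e-4, tolerance = 1e-9)
  expect_true(all(p1$g[-1] == 0))

  expect_error(compute_prdf(list(), sph, "K+"), "non-empty")
  expect_error(compute_prdf(list(matrix(0, 1, 3)), sph, "Na+"), "species")
})

test_that("uniform bulk ions reproduce g_bulk within Poisson error", {
  sph <- make_spheres(c(0, 0, 0), 2)
  r_max <- 4
  L <- 7                       # box half-width covering every shell
  lambda <- 6.02214076e-4 * (2 * L)^3   # mean ions per frame at 1 M
  set.seed(11)
  frames <- replicate(10000, {
    m <- rpois(1, lambda)
    matrix(runif(3 * m, -L, L), ncol = 3)
  }, simplify = FALSE)
  p <- compute_prdf(frames, sph, "K+", r_max = r_max)
  vols <- vapply(seq_along(p$r_mid), function(k) {
    shell_volume(sph, p$r_mid[k] - 0.25, p$r_mid[k] + 0.25, grid_step = 0.1)
  }, numeric(1))
  expect_counts <- vols * 6.02214076e-4 * 10000
  se_rel <- 1 / sqrt(expect_counts)
  expect_true(all(abs(p$g - 1) <= 3 * se_rel))
})

test_that("pRDF computation is linear in frame counts", {
  sph <- make_spheres(c(0, 0, 0), 2)
  set.seed(5)
  f1 <- replicate(40, matrix(runif(9, -5, 5), ncol = 3), simplify = FALSE)
  f2 <- replicate(60, matrix(runif(6, -5, 5), ncol = 3), simplify = FALSE)
  pa <- compute_prdf(f1, sph, "K+", r_max = 4)
  pb <- compute_prdf(f2, sph, "K+", r_max = 4)
  pc <- compute_prdf(c(f1, f2), sph, "K+", r_max = 4)
  expect_equal(pc$g, (40 * pa$g + 60 * pb$g) / 100, tolerance = 1e-9)
})

test_that("synthetic profiles are deterministic with the documented signs", {
  flat <- synthesize_prdf("GLY", "K+",
                          list(charge_class = "hydrophobic", peak_height = 0,
                               peak_pos = 3, peak_width = 1,
                               depletion_depth = 0, decay_length = 2,
                               noise_sd = 0), seed = 1)
  # flat parameters leave only the contact-exclusion rise near the surface
  expect_true(all(abs(flat$g[flat$r_mid > 6] - 1) < 1e-6))
  expect_true(all(diff(flat$g[flat$r_mid < 4]) > 0))

  a <- fixture_prdf("GLU", "K+", seed = 3)
  b <- fixture_prdf("GLU", "K+", seed = 3)
  expect_identical(a$g, b$g)
  c2 <- fixture_prdf("GLU", "K+", seed = 4)
  expect_false(identical(a$g, c2$g))

  # charge-dependent near-surface enrichment/depletion
  glu_k <- fixture_prdf("GLU", "K+")
  glu_cl <- fixture_prdf("GLU", "Cl-")
  near <- glu_k$r_mid < 5
  expect_gt(max(glu_k$g[near]), glu_k$g_bulk)
  expect_lt(min(glu_cl$g[near]), glu_cl$g_bulk)
  lys_k <- fixture_prdf("LYS", "K+")
  lys_cl <- fixture_prdf("LYS", "Cl-")
  expect_gt(max(lys_cl$g[near]), lys_cl$g_bulk)
  expect_lt(min(lys_k$g[near]), lys_k$g_bulk)
  met <- fixture_prdf("MET", "K+")
  expect_lt(min(met$g[near]), met$g_bulk)
  expect_lt(max(met$g[near]), 1.2 * met$g_bulk)  # no preference, no peak

  expect_error(synthesize_prdf("GLY", "K+",
                               list(charge_class = "charged",
                                    peak_height = 0, peak_pos = 3,
                                    peak_width = 1, depletion_depth = 0,
                                    decay_length = 2), 1),
               "charge_class")
})

test_that("bulk onset detects where profiles settle", {
  flat <- prdf("K+", "SYN", seq(0.25, 19.75, 0.5), rep(1, 40))
  expect_equal(bulk_onset(flat, 0.05), 0.25)

  g <- rep(1, 40)
  r <- seq(0.25, 19.75, 0.5)
  g[r < 12] <- 0.5
  stepped <- prdf("K+", "SYN", r, g)
  expect_lt(abs(bulk_onset(stepped, 0.05) - 12), 0.51)

  never <- prdf("K+", "SYN", r, seq(2, 4, length.out = 40))
  expect_identical(bulk_onset(never, 0.05), Inf)

  # every packaged fixture reaches bulk by 15 A and its tail averages to
  # within 10% of g_bulk
  for (res in residue_codes()) {
    for (sp in c("K+", "Cl-")) {
      p <- fixture_prdf(res, sp, seed = match(res, residue_codes()))
      expect_lte(bulk_onset(p, 0.10), 15)
      expect_lt(abs(mean(p$g[p$r_mid > 15]) - p$g_bulk) / p$g_bulk, 0.10)
    }
  }
})

test_that("implied ion excess is sign-consistent with the charge class", {
  sph <- make_spheres(c(0, 0, 0), 2)
  vols <- ionseqsim:::.shell_volumes(sph, seq(0, 15, 0.5), grid_step = 0.25)
  excess <- function(res, sp) {
    p <- fixture_prdf(res, sp, seed = 2)
    sum((p$g[1:30] - p$g_bulk) * vols)
  }
  expect_lt(excess("MET", "K+"), 0)       # hydrophobic depletes both
  expect_lt(excess("MET", "Cl-"), 0)
  expect_gt(excess("GLU", "K+"), excess("GLU", "Cl-"))   # attracts K+
  expect_gt(excess("LYS", "Cl-"), excess("LYS", "K+"))   # attracts Cl-
})

test_that("pRDF CSV round-trips and frame files parse", {
  p <- fixture_prdf("ALA", "K+", seed = 9)
  f <- tempfile(fileext = ".csv")
  write_prdf(p, f)
  q <- read_prdf(f)
  expect_equal(q$g, p$g, tolerance = 1e-9)
  expect_identical(q$species, "K+")
  expect_identical(q$residue_code, "ALA")

  ff <- tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "4 5 6", "", "7 8 9"), ff)
  frames <- read_ion_frames(ff)
  expect_length(frames, 2)
  expect_equal(frames[[1]], rbind(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(frames[[2]], rbind(c(7, 8, 9)))
})
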