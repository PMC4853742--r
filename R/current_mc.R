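# physical constants for the transverse-current formula
.Q_ELEMENTARY <- 1.602176634e-19   # C
.M3_PER_MOLAR <- 6.02214076e26     # ions per m^3 at 1 mol/L
.A2_TO_M2 <- 1e-20

#' Discretized Ramachandran density
#'
#' A grid of (phi, psi) bins with non-negative weights summing to 1,
#' covering \[-180, 180\]^2, used to sample backbone dihedrals of a
#' force-straightened chain.
#'
#' @param phi_mid,psi_mid Bin-center angles, degrees.
#' @param weight Non-negative weights (renormalized to sum 1).
#' @param bin_width Bin width in degrees (default 10).
#' @param pulling_force_pN Label for the pulling force the density
#'   represents.
#' @return Object of class `ramachandran_density`.
#' @export
ramachandran_density <- function(phi_mid, psi_mid, weight, bin_width = 10,
                                 pulling_force_pN = 250) {
  stopifnot(length(phi_mid) == length(psi_mid),
            length(phi_mid) == length(weight), length(weight) >= 1)
  if (any(weight < 0) || sum(weight) <= 0) {
    stop("weights must be non-negative with positive sum")
  }
  if (any(abs(phi_mid) > 180) || any(abs(psi_mid) > 180)) {
    stop("bin centers must lie in [-180, 180]")
  }
  structure(
    list(phi_mid = phi_mid, psi_mid = psi_mid,
         weight = weight / sum(weight), bin_width = bin_width,
         pulling_force_pN = pulling_force_pN),
    class = "ramachandran_density"
  )
}

#' Load the packaged Ramachandran density fixture
#' @param pulling_force_pN Pulling force selecting the fixture (250).
#' @return A [ramachandran_density()].
#' @export
load_ramachandran <- function(pulling_force_pN = 250) {
  fname <- sprintf("ramachandran_%dpN.csv", as.integer(pulling_force_pN))
  path <- system.file("extdata", fname, package = "ionseqsim")
  if (path == "") {
    stop("no packaged Ramachandran fixture for ", pulling_force_pN, " pN")
  }
  d <- utils::read.csv(path, comment.char = "#")
  ramachandran_density(d$phi_mid_deg, d$psi_mid_deg, d$weight,
                       pulling_force_pN = pulling_force_pN)
}

# draw n (phi, psi) pairs: bin by weight, uniform jitter within the bin
.sample_dihedrals <- function(rd, n) {
  idx <- sample.int(length(rd$weight), n, replace = TRUE, prob = rd$weight)
  h <- rd$bin_width / 2
  phi <- rd$phi_mid[idx] + stats::runif(n, -h, h)
  psi <- rd$psi_mid[idx] + stats::runif(n, -h, h)
  list(phi = pmax(pmin(phi, 180), -180), psi = pmax(pmin(psi, 180), -180))
}

#' Monte Carlo transverse ionic current distribution for one residue
#'
#' For each draw, samples backbone dihedrals from the Ramachandran density,
#' an azimuth uniform on \[0, 360) degrees (tilt fixed at 0), applies the
#' conformation, and measures the free area of the y = 0 cross-section
#' outside the effective surface for each ion species (atom radii inflated
#' by that species' effective radius). Both species share the conformation;
#' the observable is the summed current
#' `I = sum_species q * g_bulk * v_bulk * A_species` in nA.
#'
#' @param s An [aa_structure()].
#' @param reff Named numeric with effective radii in Angstrom for `"K+"`
#'   and `"Cl-"`.
#' @param rd A [ramachandran_density()].
#' @param vp A [velocity_profile()] (supplies `v_bulk` and the channel
#'   radius `R`; the measurement disk has radius R/2).
#' @param n Number of Monte Carlo draws (default 1e5).
#' @param seed Integer seed (same seed, same samples).
#' @param g_bulk Bulk concentration, mol/L.
#' @param z_margin z-window margin, Angstrom (default 1.9).
#' @param grid_step Plane grid spacing for the free-area measurement,
#'   Angstrom (default 0.05).
#' @param n_bins Histogram bins for the returned distribution.
#' @return A `current_distribution` (see [build_distribution()]).
#' @export
sample_currents <- function(s, reff, rd, vp, n = 1e5, seed = 1L,
                            g_bulk = 1.0, z_margin = 1.9, grid_step = 0.05,
                            n_bins = 100) {
  stopifnot(inherits(s, "aa_structure"),
            inherits(rd, "ramachandran_density"),
            inherits(vp, "velocity_profile"), n >= 1)
  if (!all(c("K+", "Cl-") %in% names(reff))) {
    stop("reff must be named with both species \"K+\" and \"Cl-\"")
  }
  samples <- .with_seed(seed, {
    dih <- .sample_dihedrals(rd, n)
    azim <- stats::runif(n, 0, 360)
    .currents_for_conformations(s, reff, vp, dih$phi, dih$psi, azim,
                                g_bulk, z_margin, grid_step)
  })
  d <- build_distribution(samples, n_bins = n_bins,
                          residue_code = s$residue_code, seed = seed,
                          allow_point_mass = TRUE)
  d
}

# free areas and summed currents for explicit conformation angles
.currents_for_conformations <- function(s, reff, vp, phi, psi, azim,
                                        g_bulk = 1.0, z_margin = 1.9,
                                        grid_step = 0.05) {
  disk <- vp$R / 2
  bb <- s$backbone
  p <- .coords(s)
  if (!is.null(bb)) {
    pN <- p[bb[1], ]; pCA <- p[bb[2], ]; pC <- p[bb[3], ]
    part <- .dihedral_partition(s)
  } else {
    pN <- pCA <- pC <- numeric(0)
    part <- integer(nrow(p))
  }
  term <- s$atoms$name %in% c(.n_terminus_atoms, .c_terminus_atoms)
  if (!any(term)) term <- rep(TRUE, nrow(p))
  areas <- cpp_sample_areas(p, if (nrow(p)) s$atoms$vdw else numeric(0),
                            part, as.integer(term), pN, pCA, pC,
                            phi, psi, azim,
                            reff[["K+"]], reff[["Cl-"]],
                            disk, z_margin, grid_step)
  .current_nA(areas[, 1], g_bulk, vp$v_bulk) +
    .current_nA(areas[, 2], g_bulk, vp$v_bulk)
}

# transverse current (nA) carried by one species through a free area (A^2)
.current_nA <- function(area_A2, g_bulk, v_bulk) {
  .Q_ELEMENTARY * (g_bulk * .M3_PER_MOLAR) * v_bulk *
    (area_A2 * .A2_TO_M2) * 1e9
}
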