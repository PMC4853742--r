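#' @useDynLib ionseqsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Three-letter codes of the 20 proteinogenic amino acids
#' @return Character vector of length 20.
#' @export
residue_codes <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# atom names making up the two chain termini of an isolated residue
.n_terminus_atoms <- c("N", "H", "H2", "H3")
.c_terminus_atoms <- c("C", "O", "OXT", "HXT")

#' Construct an amino-acid structure
#'
#' An `aa_structure` holds the atoms of one residue (element, position in
#' Angstrom, van der Waals radius in Angstrom), centered so the geometric
#' center of its backbone atoms lies on the z axis, with z the longitudinal
#' (translocation) direction. Synthetic test shapes use `residue_code =
#' "SYN"` and may omit backbone information (and, for point-free reference
#' windows, atoms altogether).
#'
#' @param residue_code Three-letter residue code or `"SYN"`.
#' @param atoms `data.frame` with columns `name`, `element`, `x`, `y`, `z`,
#'   `vdw` (radius, Angstrom). May have zero rows only for `"SYN"`.
#' @param backbone Integer indices (into `atoms`) of the backbone N, CA, C
#'   atoms in that order, or `NULL` for synthetic shapes without a backbone.
#' @return Object of class `aa_structure`.
#' @export
aa_structure <- function(residue_code, atoms, backbone = NULL) {
  stopifnot(is.character(residue_code), length(residue_code) == 1)
  if (!(residue_code %in% residue_codes() || residue_code == "SYN")) {
    stop("unknown residue code: ", residue_code)
  }
  atoms <- as.data.frame(atoms)
  need <- c("name", "element", "x", "y", "z", "vdw")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(atoms) == 0 && residue_code != "SYN") {
    stop("a residue structure needs at least one atom")
  }
  if (nrow(atoms) > 0 && any(!is.finite(atoms$vdw) | atoms$vdw <= 0)) {
    stop("all vdW radii must be positive and finite")
  }
  if (!is.null(backbone)) {
    stopifnot(length(backbone) == 3, all(backbone %in% seq_len(nrow(atoms))))
  }
  s <- structure(
    list(residue_code = residue_code, atoms = atoms, backbone = backbone),
    class = "aa_structure"
  )
  s$terminal_z_extent <- .terminal_z_extent(s)
  s
}

# largest |z| reached by the vdW spheres of the chain-terminus atoms;
# falls back to the whole structure when no backbone naming is present
.terminal_z_extent <- function(s) {
  a <- s$atoms
  if (nrow(a) == 0) return(0)
  sel <- a$name %in% c(.n_terminus_atoms, .c_terminus_atoms)
  if (!any(sel)) sel <- rep(TRUE, nrow(a))
  max(abs(a$z[sel]) + a$vdw[sel])
}

.coords <- function(s) {
  if (nrow(s$atoms) == 0) {
    return(matrix(numeric(0), ncol = 3))
  }
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' @export
print.aa_structure <- function(x, ...) {
  cat(sprintf("<aa_structure %s: %d atoms, terminal z extent %.2f A>\n",
              x$residue_code, nrow(x$atoms), x$terminal_z_extent))
  invisible(x)
}

#' Load a packaged residue template
#'
#' Templates are single amino acids isolated from a straight (phi = psi =
#' 180 degrees) chain, with N-terminal H and C-terminal OH caps, centered
#' with the backbone (N, CA, C) centroid at the origin and the N-to-C
#' direction along +z. vdW radii come from the packaged Bondi element set.
#'
#' @param code Three-letter residue code (e.g. `"LYS"`).
#' @return An [aa_structure()].
#' @export
load_residue_template <- function(code) {
  stopifnot(is.character(code), length(code) == 1)
  code <- toupper(code)
  if (!code %in% residue_codes()) {
    stop("unknown residue code: ", code)
  }
  pdb_file <- system.file("extdata", "templates", paste0(code, ".pdb"),
                          package = "ionseqsim")
  if (pdb_file == "") stop("no packaged template for residue ", code)
  pdb <- tryCatch(
    bio3d::read.pdb(pdb_file, verbose = FALSE),
    error = function(e) stop("malformed PDB template ", pdb_file, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  radii <- .vdw_radii()
  elem <- trimws(at$elesy)
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown) > 0) {
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "))
  }
  atoms <- data.frame(
    name = trimws(at$elety), element = elem,
    x = at$x, y = at$y, z = at$z,
    vdw = unname(radii[elem]),
    stringsAsFactors = FALSE
  )
  backbone <- match(c("N", "CA", "C"), atoms$name)
  if (anyNA(backbone)) stop("template ", code, " lacks backbone N/CA/C atoms")
  aa_structure(code, atoms, backbone)
}

.vdw_radii <- function() {
  path <- system.file("extdata", "vdw_radii.json", package = "ionseqsim")
  j <- jsonlite::fromJSON(path)
  unlist(j$radii)
}

#' Construct a conformation
#'
#' Backbone dihedrals phi/psi, azimuthal rotation about z, and tilt (fixed
#' at 0 in production paths: the peptide bond is rigid). The template is the
#' extended chain, so dihedral rotations are applied as deltas
#' (phi - 180, psi - 180) relative to it.
#'
#' @param phi,psi Backbone dihedrals in degrees, in \[-180, 180\].
#' @param azimuth Rotation about z in degrees.
#' @param tilt Must be 0.
#' @return Object of class `conformation`.
#' @export
conformation <- function(phi = 180, psi = 180, azimuth = 0, tilt = 0) {
  stopifnot(is.finite(phi), is.finite(psi), is.finite(azimuth))
  if (tilt != 0) stop("tilt is fixed at 0")
  structure(list(phi = phi, psi = psi, azimuth = azimuth, tilt = 0),
            class = "conformation")
}

# rotate points (n x 3) about axis through `origin` with direction `axis`
.rotate_about_axis <- function(p, origin, axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  v <- sweep(p, 2, origin)
  dot <- drop(v %*% u)
  crs <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
               u[3] * v[, 1] - u[1] * v[, 3],
               u[1] * v[, 2] - u[2] * v[, 1])
  out <- v * ca + crs * sa + outer(dot * (1 - ca), u)
  sweep(out, 2, origin, "+")
}

# phi rotates the N-side cap hydrogens about N-CA; psi rotates the carboxyl
# group about CA-C; everything else (CA, side chain) is the rigid core
.dihedral_partition <- function(s) {
  nm <- s$atoms$name
  part <- integer(length(nm))
  part[nm %in% c("H", "H2", "H3")] <- 1L
  part[nm %in% c("O", "OXT", "HXT")] <- 2L
  part
}

#' Apply a conformation to a structure
#'
#' Rigid rotations: the phi-side atoms rotate about the N-CA axis by
#' (phi - 180), the psi-side atoms about the CA-C axis by (psi - 180), then
#' the whole structure rotates about z by the azimuth. Bond lengths and all
#' intra-rigid-body distances are preserved exactly (orthogonal maps).
#'
#' @param s An [aa_structure()].
#' @param conf A [conformation()].
#' @return A new `aa_structure` with transformed coordinates.
#' @export
apply_conformation <- function(s, conf) {
  stopifnot(inherits(s, "aa_structure"), inherits(conf, "conformation"))
  p <- .coords(s)
  if (nrow(p) > 0 && !is.null(s$backbone)) {
    part <- .dihedral_partition(s)
    pN <- p[s$backbone[1], ]
    pCA <- p[s$backbone[2], ]
    pC <- p[s$backbone[3], ]
    if (any(part == 1L)) {
      p[part == 1L, ] <- .rotate_about_axis(
        p[part == 1L, , drop = FALSE], pN, pCA - pN, conf$phi - 180)
    }
    if (any(part == 2L)) {
      p[part == 2L, ] <- .rotate_about_axis(
        p[part == 2L, , drop = FALSE], pCA, pC - pCA, conf$psi - 180)
    }
  }
  if (nrow(p) > 0) {
    a <- conf$azimuth * pi / 180
    rot <- p
    rot[, 1] <- p[, 1] * cos(a) - p[, 2] * sin(a)
    rot[, 2] <- p[, 1] * sin(a) + p[, 2] * cos(a)
    p <- rot
  }
  out <- s
  out$atoms$x <- p[, 1]
  out$atoms$y <- p[, 2]
  out$atoms$z <- p[, 3]
  out$terminal_z_extent <- .terminal_z_extent(out)
  out
}

# quasi-uniform unit directions (Fibonacci sphere)
.fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Mean radius from the origin to the vdW surface
#'
#' Averages, over quasi-uniform directions, the distance from the origin to
#' the outermost crossing of the union-of-spheres surface. The origin must
#' lie inside the union.
#'
#' @param s An [aa_structure()].
#' @param n_directions Number of quasi-uniform ray directions.
#' @return Mean surface radius in Angstrom.
#' @export
mean_surface_radius <- function(s, n_directions = 1e5) {
  stopifnot(inherits(s, "aa_structure"), n_directions >= 1)
  p <- .coords(s)
  if (nrow(p) == 0) stop("structure has no atoms")
  vdw <- s$atoms$vdw
  if (min(sqrt(rowSums(p^2)) - vdw) > 0) {
    stop("origin lies outside the vdW surface")
  }
  dirs <- .fibonacci_directions(as.integer(n_directions))
  # per atom: outer ray-sphere crossing t = b + sqrt(b^2 - |c|^2 + r^2)
  b <- dirs %*% t(p)                       # n_dir x n_atoms
  disc <- sweep(b^2, 2, rowSums(p^2), "-")
  disc <- sweep(disc, 2, vdw^2, "+")
  tmax <- b + sqrt(pmax(disc, 0))
  tmax[disc < 0] <- -Inf
  mean(apply(tmax, 1, max))
}

#' Volume of a surface-distance shell
#'
#' Volume of the set of points whose perpendicular distance from the vdW
#' surface lies in `[r_lo, r_hi)`, outside the molecule, computed by
#' counting grid cells (cell volume `grid_step^3`).
#'
#' @param s An [aa_structure()].
#' @param r_lo,r_hi Shell bounds from the surface, Angstrom.
#' @param grid_step Grid spacing, Angstrom (default 0.1).
#' @return Volume in cubic Angstrom.
#' @export
shell_volume <- function(s, r_lo, r_hi, grid_step = 0.1) {
  stopifnot(inherits(s, "aa_structure"),
            is.finite(r_lo), is.finite(r_hi), grid_step > 0,
            r_lo >= 0, r_lo <= r_hi)
  if (r_lo == r_hi) return(0)
  drop(cpp_shell_volumes(.coords(s), s$atoms$vdw, c(r_lo, r_hi), grid_step))
}

# volumes of all shells [breaks[i], breaks[i+1]) in one grid pass
.shell_volumes <- function(s, breaks, grid_step = 0.1) {
  cpp_shell_volumes(.coords(s), s$atoms$vdw, breaks, grid_step)
}

#' Free area of the measurement cross-section
#'
#' Area of the y = 0 disk of radius `disk_radius`, clipped to the z window
#' `|z| <= terminal_z_extent + z_margin`, lying outside every circle cut by
#' the plane from the atoms' spheres inflated by `inflate_by`. The z clip
#' discards portions of the cross-section dominated by the neighboring
#' residues in a chain; use `z_margin = Inf` for the unclipped disk.
#'
#' @param s An [aa_structure()].
#' @param inflate_by Radius added to every atom's vdW radius (e.g. an
#'   effective radius), Angstrom.
#' @param disk_radius Radius of the circular boundary, Angstrom.
#' @param z_margin Half inter-residue spacing added to the terminal z
#'   extent (default 1.9, half of 3.8 A).
#' @param grid_step Plane grid spacing, Angstrom (default 0.05).
#' @return Area in square Angstrom.
#' @export
plane_exclusion_area <- function(s, inflate_by, disk_radius,
                                 z_margin = 1.9, grid_step = 0.05) {
  stopifnot(inherits(s, "aa_structure"), is.finite(inflate_by),
            inflate_by >= 0, is.finite(disk_radius), disk_radius > 0,
            grid_step > 0, z_margin >= 0)
  zw <- .z_window(s, z_margin)
  cpp_plane_free_area(.coords(s), if (nrow(s$atoms)) s$atoms$vdw else numeric(0),
                      inflate_by, disk_radius, zw, grid_step)
}

.z_window <- function(s, z_margin) {
  if (!is.finite(z_margin)) return(Inf)
  s$terminal_z_extent + z_margin
}
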