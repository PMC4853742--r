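#' Transverse velocity profile past a residue
#'
#' Dimensionless parabolic flow-ratio profile with no-slip at the molecular
#' surface and at the channel wall. The ratio reaches its maximum of
#' exactly 1 at `r_b = (R - r_o) / 2`, the distance from the surface where
#' the flow (and the ion concentration) is in the bulk.
#'
#' @param r_o Mean surface radius of the residue, Angstrom.
#' @param R Channel radius, Angstrom (default 35).
#' @param v_bulk Bulk transverse velocity, m/s (default 77.23).
#' @return Object of class `velocity_profile` with fields `r_o`, `R`,
#'   `r_b`, `v_bulk`.
#' @export
velocity_profile <- function(r_o, R = 35, v_bulk = 77.23) {
  stopifnot(is.finite(r_o), r_o > 0, R > r_o, v_bulk > 0)
  structure(list(r_o = r_o, R = R, r_b = (R - r_o) / 2, v_bulk = v_bulk),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile: r_o %.2f A, R %.1f A, r_b %.2f A, v_bulk %.2f m/s>\n",
              x$r_o, x$R, x$r_b, x$v_bulk))
  invisible(x)
}

#' Velocity ratio v / v_bulk at a distance from the surface
#'
#' `1 - ((r - r_b) / r_b)^2` on `[0, 2 r_b]`, clipped to `[0, 1]`, and 0
#' beyond; vectorized in `r_gt`.
#'
#' @param p A [velocity_profile()].
#' @param r_gt Distance(s) from the vdW surface, Angstrom, non-negative.
#' @return Dimensionless ratio(s) in `[0, 1]`.
#' @export
velocity_ratio <- function(p, r_gt) {
  stopifnot(inherits(p, "velocity_profile"))
  if (any(!is.finite(r_gt)) || any(r_gt < 0)) {
    stop("r_gt must be finite and non-negative")
  }
  ratio <- 1 - ((r_gt - p$r_b) / p$r_b)^2
  ratio[r_gt > 2 * p$r_b] <- 0
  pmin(pmax(ratio, 0), 1)
}
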