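# dense grid size used for normalization, sampling and fast density lookup
.DIST_GRID_N <- 4097L

#' Build a current distribution from Monte Carlo samples
#'
#' Histograms the samples (density-normalized), interpolates the bin-center
#' densities with a natural cubic spline, clips negative excursions to 0
#' and renormalizes so the PDF integrates to 1 over the sample range.
#'
#' @param samples Numeric vector of currents (nA), at least 2 distinct
#'   values (a point mass is only representable with
#'   `allow_point_mass = TRUE`).
#' @param n_bins Number of histogram bins (default 100).
#' @param residue_code Label carried by the distribution.
#' @param seed Seed recorded as metadata (not used here).
#' @param allow_point_mass Return a flagged degenerate distribution instead
#'   of erroring when all samples are identical.
#' @return Object of class `current_distribution` with the histogram
#'   (`breaks`, `mids`, `masses`), the spline `pdf` function, `support`,
#'   `samples`, `n_samples` and `seed`.
#' @export
build_distribution <- function(samples, n_bins = 100, residue_code = "SYN",
                               seed = NA_integer_,
                               allow_point_mass = FALSE) {
  samples <- as.numeric(samples)
  stopifnot(length(samples) >= 1, all(is.finite(samples)), n_bins >= 2)
  rng <- range(samples)
  if (rng[1] == rng[2]) {
    if (!allow_point_mass) {
      stop("all samples are identical; degenerate (point mass) distribution")
    }
    d <- structure(
      list(residue_code = residue_code, point_mass = TRUE, at = rng[1],
           samples = samples, n_samples = length(samples), seed = seed,
           support = rng),
      class = "current_distribution"
    )
    return(d)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  width <- diff(breaks)[1]
  cnt <- tabulate(findInterval(samples, breaks, rightmost.closed = TRUE),
                  nbins = n_bins)
  masses <- cnt / length(samples)
  mids <- breaks[-1] - width / 2
  spl <- stats::splinefun(mids, masses / width, method = "natural")
  grid_x <- seq(rng[1], rng[2], length.out = .DIST_GRID_N)
  raw <- pmax(spl(grid_x), 0)
  z <- .trapz(grid_x, raw)
  if (z <= 0) stop("spline density collapsed to zero")
  pdf_fun <- local({
    spl_l <- spl; z_l <- z; lo <- rng[1]; hi <- rng[2]
    function(x) {
      out <- numeric(length(x))
      ok <- x >= lo & x <= hi
      out[ok] <- pmax(spl_l(x[ok]), 0) / z_l
      out
    }
  })
  dens <- raw / z
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(grid_x)))
  cdf <- cdf / cdf[length(cdf)]
  structure(
    list(residue_code = residue_code, point_mass = FALSE,
         breaks = breaks, mids = mids, masses = masses,
         pdf = pdf_fun, support = rng,
         grid_x = grid_x, grid_pdf = dens, grid_cdf = cdf,
         samples = samples, n_samples = length(samples), seed = seed),
    class = "current_distribution"
  )
}

.trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Wrap a known density as a current distribution
#'
#' Builds a `current_distribution` directly from a density function
#' (normalized over `support`), e.g. to compare the classifier against
#' closed-form cases.
#'
#' @param f Vectorized density function.
#' @param support Length-2 numeric range.
#' @param residue_code Label.
#' @return A `current_distribution`.
#' @export
distribution_from_density <- function(f, support, residue_code = "SYN") {
  stopifnot(is.function(f), length(support) == 2, support[1] < support[2])
  grid_x <- seq(support[1], support[2], length.out = .DIST_GRID_N)
  raw <- pmax(f(grid_x), 0)
  z <- .trapz(grid_x, raw)
  if (z <= 0) stop("density integrates to zero over the support")
  pdf_fun <- local({
    f_l <- f; z_l <- z; lo <- support[1]; hi <- support[2]
    function(x) {
      out <- numeric(length(x))
      ok <- x >= lo & x <= hi
      out[ok] <- pmax(f_l(x[ok]), 0) / z_l
      out
    }
  })
  dens <- raw / z
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(grid_x)))
  cdf <- cdf / cdf[length(cdf)]
  structure(
    list(residue_code = residue_code, point_mass = FALSE,
         breaks = NULL, mids = NULL, masses = NULL,
         pdf = pdf_fun, support = as.numeric(support),
         grid_x = grid_x, grid_pdf = dens, grid_cdf = cdf,
         samples = NULL, n_samples = NA_integer_, seed = NA_integer_),
    class = "current_distribution"
  )
}

#' @export
print.current_distribution <- function(x, ...) {
  if (isTRUE(x$point_mass)) {
    cat(sprintf("<current_distribution %s: point mass at %.3f nA>\n",
                x$residue_code, x$at))
  } else {
    cat(sprintf(
      "<current_distribution %s: support [%.2f, %.2f] nA, n = %s>\n",
      x$residue_code, x$support[1], x$support[2],
      if (is.na(x$n_samples)) "analytic" else format(x$n_samples)))
  }
  invisible(x)
}

#' Evaluate the probability density of a current distribution
#' @param d A `current_distribution`.
#' @param x Currents (nA).
#' @return Density values (0 outside the support).
#' @export
dist_density <- function(d, x) {
  stopifnot(inherits(d, "current_distribution"))
  if (isTRUE(d$point_mass)) stop("point-mass distribution has no density")
  d$pdf(x)
}

#' Draw random currents from a distribution (inverse-CDF on a dense grid)
#' @param d A `current_distribution`.
#' @param n Number of draws.
#' @return Numeric vector of currents (nA). Uses the current RNG stream.
#' @export
dist_sample <- function(d, n) {
  stopifnot(inherits(d, "current_distribution"), n >= 1)
  if (isTRUE(d$point_mass)) return(rep(d$at, n))
  u <- stats::runif(n)
  stats::approx(d$grid_cdf, d$grid_x, xout = u, ties = "ordered",
                rule = 2)$y
}

# fast log-density lookup on the dense grid (linear interpolation);
# -Inf outside the support or where the pdf is zero
.dist_log_density_grid <- function(d, x) {
  out <- rep(-Inf, length(x))
  ok <- x >= d$support[1] & x <= d$support[2]
  if (any(ok)) {
    v <- stats::approx(d$grid_x, d$grid_pdf, xout = x[ok], rule = 2)$y
    out[ok] <- ifelse(v > 0, log(v), -Inf)
  }
  out
}
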