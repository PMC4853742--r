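# Synthetic structures and independent oracles used across the suite.

# SYN structure from sphere centers (n x 3) and radii; no backbone unless
# backbone indices are given
make_spheres <- function(centers, radii, backbone = NULL) {
  centers <- matrix(centers, ncol = 3)
  atoms <- data.frame(
    name = paste0("S", seq_len(nrow(centers))),
    element = "C",
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    vdw = radii, stringsAsFactors = FALSE
  )
  aa_structure("SYN", atoms, backbone)
}

point_free_structure <- function() {
  aa_structure("SYN", data.frame(name = character(0), element = character(0),
                                 x = numeric(0), y = numeric(0),
                                 z = numeric(0), vdw = numeric(0)))
}

# mean surface radius of two equal spheres on the z axis, by quadrature over
# the polar angle (axisymmetric; independent of the ray-sampling estimator)
two_sphere_mean_radius_oracle <- function(a, c0) {
  ray_r <- function(u) {  # u = cos(theta); direction (sin, 0, cos)
    sapply(u, function(ui) {
      best <- -Inf
      for (zc in c(-c0, c0)) {
        b <- ui * zc
        disc <- b^2 - c0^2 + a^2
        if (disc >= 0) best <- max(best, b + sqrt(disc))
      }
      best
    })
  }
  stats::integrate(ray_r, -1, 1, rel.tol = 1e-10)$value / 2
}

# Monte Carlo rejection-sampling volume of a surface-distance shell
mc_shell_volume_oracle <- function(s, r_lo, r_hi, n = 1e7, seed = 42) {
  set.seed(seed)
  p <- as.matrix(s$atoms[, c("x", "y", "z")])
  vdw <- s$atoms$vdw
  lo <- apply(p - (vdw + r_hi), 2, min)
  hi <- apply(p + (vdw + r_hi), 2, max)
  vol_box <- prod(hi - lo)
  inside <- 0
  chunk <- 1e6
  done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    pts <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                 runif(m, lo[3], hi[3]))
    d <- rep(Inf, m)
    for (i in seq_len(nrow(p))) {
      d <- pmin(d, sqrt((pts[, 1] - p[i, 1])^2 + (pts[, 2] - p[i, 2])^2 +
                        (pts[, 3] - p[i, 3])^2) - vdw[i])
    }
    inside <- inside + sum(d >= r_lo & d < r_hi)
    done <- done + m
  }
  vol_box * inside / n
}

# analytic area of a disk of radius D clipped to |z| <= zw
clipped_disk_area <- function(D, zw) {
  if (zw >= D) return(pi * D^2)
  2 * (zw * sqrt(D^2 - zw^2) + D^2 * asin(zw / D))
}

# Monte Carlo rejection-sampling free area of the clipped disk outside the
# inflated sphere slices
mc_plane_area_oracle <- function(s, inflate, disk_radius, z_window,
                                 n = 1e7, seed = 42) {
  set.seed(seed)
  p <- as.matrix(s$atoms[, c("x", "y", "z")])
  vdw <- s$atoms$vdw
  free <- 0
  total <- 0
  chunk <- 1e6
  done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    x <- runif(m, -disk_radius, disk_radius)
    z <- runif(m, -disk_radius, disk_radius)
    inw <- x^2 + z^2 <= disk_radius^2 & abs(z) <= z_window
    x <- x[inw]; z <- z[inw]
    total <- total + sum(inw)
    if (length(x) > 0) {
      d <- rep(Inf, length(x))
      for (i in seq_len(nrow(p))) {
        d <- pmin(d, sqrt((x - p[i, 1])^2 + p[i, 2]^2 + (z - p[i, 3])^2) -
                    vdw[i])
      }
      free <- free + sum(d >= inflate)
    }
    done <- done + m
  }
  (2 * disk_radius)^2 * free / n
}

# brute-force effective-radius scan on a fine candidate grid (independent of
# the bisection solver; shares only the shell-area integrand)
brute_force_reff <- function(s, p, vp, r_upper, grid = 1e-4,
                             grid_step = 0.05) {
  dr <- p$shell_thickness
  n <- ceiling(r_upper / dr - 1e-9)
  breaks <- seq(0, by = dr, length.out = n + 1)
  r_mid <- breaks[-1] - dr / 2
  a_band <- sapply(seq_len(n), function(k) {
    shell_plane_area(s, r_mid[k], thickness = dr, grid_step = grid_step)
  })
  vr <- if (is.null(vp)) rep(1, n) else velocity_ratio(vp, r_mid)
  rhs <- sum((p$g[seq_len(n)] / p$g_bulk) * vr * a_band)
  xs <- seq(0, r_upper, by = grid)
  # L(x): remaining area beyond x, piecewise linear within shells
  k <- pmin(findInterval(xs, breaks, rightmost.closed = TRUE), n)
  tail_sums <- c(rev(cumsum(rev(a_band))), 0)
  Lx <- tail_sums[k + 1] + a_band[k] * (breaks[k + 1] - xs) / dr
  Lx[xs >= r_upper] <- 0
  xs[which.min(abs(Lx - rhs))]
}

# shared small-scale pipeline for acceptance-style tests, computed once
.pipeline_cache <- new.env(parent = emptyenv())
acceptance_pipeline <- function() {
  if (is.null(.pipeline_cache$out)) {
    cfg <- run_config(n_samples = 2e4, J = 1000, M = 175, M_values = 175,
                      seed = 20260924L)
    .pipeline_cache$out <- run_pipeline(cfg, out_dir = NULL, verbose = FALSE)
  }
  .pipeline_cache$out
}
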