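#' Run configuration
#'
#' Collects the physical and numerical parameters of a full simulation
#' run. Defaults follow the reference operating point of the model: a
#' 35 Angstrom channel at 310 K filled with 1 M KCl, bulk transverse
#' velocity 77.23 m/s, a 250 pN pulling force selecting the packaged
#' Ramachandran fixture.
#'
#' @param channel_radius_A Channel radius R, Angstrom.
#' @param disk_radius_A Measurement disk radius (default R/2; must not
#'   exceed R/2).
#' @param g_bulk_molar Bulk ion concentration, mol/L.
#' @param v_bulk_m_per_s Bulk transverse velocity, m/s.
#' @param temperature_K Temperature (metadata only).
#' @param pulling_force_pN Pulling force; selects the Ramachandran fixture.
#' @param n_samples Monte Carlo draws per residue.
#' @param n_bins Histogram bins per distribution.
#' @param mc_grid_step_A Plane grid spacing for the Monte Carlo free-area
#'   measurement, Angstrom.
#' @param J Realizations per residue in the error estimate.
#' @param M Measurements per residue for the headline error/protocol.
#' @param M_values M grid for the error curve.
#' @param measurement_frequency_Hz Measurement frequency for the protocol
#'   report.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(channel_radius_A = 35,
                       disk_radius_A = channel_radius_A / 2,
                       g_bulk_molar = 1.0,
                       v_bulk_m_per_s = 77.23,
                       temperature_K = 310,
                       pulling_force_pN = 250,
                       n_samples = 1e5,
                       n_bins = 100,
                       mc_grid_step_A = 0.05,
                       J = 1000,
                       M = 175,
                       M_values = c(1, seq(5, 200, by = 5)),
                       measurement_frequency_Hz = 1e5,
                       seed = 1L) {
  cfg <- list(channel_radius_A = channel_radius_A,
              disk_radius_A = disk_radius_A,
              g_bulk_molar = g_bulk_molar,
              v_bulk_m_per_s = v_bulk_m_per_s,
              temperature_K = temperature_K,
              pulling_force_pN = pulling_force_pN,
              n_samples = n_samples, n_bins = n_bins,
              mc_grid_step_A = mc_grid_step_A,
              J = J, M = M, M_values = M_values,
              measurement_frequency_Hz = measurement_frequency_Hz,
              seed = as.integer(seed))
  pos <- c("channel_radius_A", "disk_radius_A", "g_bulk_molar",
           "v_bulk_m_per_s", "temperature_K", "pulling_force_pN",
           "n_samples", "n_bins", "mc_grid_step_A", "J", "M",
           "measurement_frequency_Hz")
  for (k in pos) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0) stop(k, " must be positive")
  }
  if (disk_radius_A > channel_radius_A / 2 + 1e-9) {
    stop("disk_radius_A must not exceed channel_radius_A / 2")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [run_config()]; unknown keys error.
#'
#' @param path File path ending in .yaml/.yml or .json.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    stop("config must be .yaml, .yml or .json: ", path)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}

# stage seeds derived from the master seed (kept far apart and < 2^31)
.stage_seed <- function(cfg, stage, k = 0L) {
  base <- c(prdf = 1000L, mc = 2000L, error = 3000L)[[stage]]
  (cfg$seed %% 100000L) * 10000L + base + as.integer(k)
}

#' Run the full simulation pipeline
#'
#' templates -> fixture pRDFs -> effective radii -> Monte Carlo current
#' distributions -> error curve -> protocol report. Artifacts (CSV/JSON)
#' are written under `out_dir`, stamped with the config hash and seeds;
#' the run is deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing), or `NULL` to
#'   skip writing files.
#' @param residues Residue codes to process (default all 20).
#' @param verbose Log progress to stderr.
#' @return List with `effective_radii` (data.frame), `distributions`
#'   (named list), `error_curve`, `protocol`, `config`, `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         residues = residue_codes(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  hash <- config_hash(config)
  rd <- load_ramachandran(config$pulling_force_pN)

  say("ionseqsim pipeline: %d residues, n = %g draws, config %s",
      length(residues), config$n_samples, hash)
  reff_rows <- list()
  dists <- list()
  for (res in residues) {
    s <- load_residue_template(res)
    r_o <- mean_surface_radius(s, 2e4)
    vp <- velocity_profile(r_o, R = config$channel_radius_A,
                           v_bulk = config$v_bulk_m_per_s)
    reff <- c("K+" = NA_real_, "Cl-" = NA_real_)
    for (sp in c("K+", "Cl-")) {
      p <- fixture_prdf(res, sp,
                        seed = .stage_seed(config, "prdf",
                                           match(res, residue_codes())))
      er <- solve_effective_radius(s, p, vp)
      reff[[sp]] <- er$r_eff
      reff_rows[[length(reff_rows) + 1]] <- data.frame(
        residue = res, species = sp, r_eff_A = er$r_eff,
        r_upper_A = er$r_upper, residual = er$residual, r_o_A = r_o,
        stringsAsFactors = FALSE)
    }
    d <- sample_currents(s, reff, rd, vp, n = config$n_samples,
                         seed = .stage_seed(config, "mc",
                                            match(res, residue_codes())),
                         g_bulk = config$g_bulk_molar,
                         grid_step = config$mc_grid_step_A,
                         n_bins = config$n_bins)
    if (config$n_samples < 1000) {
      warning("n_samples = ", config$n_samples,
              " is small; spline density for ", res,
              " may be poorly resolved")
    }
    dists[[res]] <- d
    say("  %s: r_o %.2f A, r_eff K+ %.2f / Cl- %.2f A, current [%.1f, %.1f] nA",
        res, r_o, reff[["K+"]], reff[["Cl-"]],
        d$support[1], d$support[2])
  }
  reff_tab <- do.call(rbind, reff_rows)

  ec <- NULL
  if (length(dists) >= 2) {
    say("error curve: J = %d, %d M values", config$J, length(config$M_values))
    ec <- error_curve(dists, M_values = config$M_values, J = config$J,
                      seed = .stage_seed(config, "error"))
  }
  pr <- protocol_report(config$measurement_frequency_Hz, config$M)

  out <- list(effective_radii = reff_tab, distributions = dists,
              error_curve = ec, protocol = pr, config = config,
              config_hash = hash)
  if (!is.null(out_dir)) .write_artifacts(out, out_dir)
  out
}

#' Hash of a run configuration
#' @param config A [run_config()].
#' @return Character md5 hash of the serialized configuration.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.write_artifacts <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = out$config_hash, seed = out$config$seed)
  reff <- out$effective_radii
  utils::write.csv(reff, file.path(out_dir, "effective_radii.csv"),
                   row.names = FALSE)
  for (res in names(out$distributions)) {
    d <- out$distributions[[res]]
    payload <- if (isTRUE(d$point_mass)) {
      list(residue = res, mc_seed = d$seed, n = d$n_samples,
           point_mass = TRUE, at = d$at)
    } else {
      list(residue = res, mc_seed = d$seed, n = d$n_samples,
           bin_edges = d$breaks, masses = d$masses, support = d$support,
           spline_knots_nA = d$mids,
           spline_density = d$masses / diff(d$breaks))
    }
    jsonlite::write_json(
      c(stamp, payload),
      file.path(out_dir, paste0("distribution_", res, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out$error_curve)) {
    utils::write.csv(as.data.frame(out$error_curve),
                     file.path(out_dir, "error_curve.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    c(stamp, unclass(out$protocol)),
    file.path(out_dir, "protocol_report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
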