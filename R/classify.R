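#' Maximum-likelihood misidentification error
#'
#' For each true residue X and each of J realizations, draws M currents
#' i.i.d. from X's distribution, computes the product likelihood of the
#' block under every candidate distribution, and counts the realization as
#' an error if any other candidate's likelihood is greater than or equal
#' to the true one (a tie counts as an error, H(0) = 1). Returns 100 times
#' the mean over residues and realizations.
#'
#' @param dists List of `current_distribution` objects (named by residue,
#'   or carrying `residue_code`s).
#' @param M Measurements per identification.
#' @param J Realizations per residue (default 1000).
#' @param seed Integer seed.
#' @return Error percentage in `[0, 100]`.
#' @export
ml_error <- function(dists, M, J = 1000, seed = 1L) {
  dists <- .check_dists(dists)
  stopifnot(M >= 1, J >= 1)
  nd <- length(dists)
  .with_seed(seed, {
    err <- 0
    for (xi in seq_len(nd)) {
      x <- matrix(dist_sample(dists[[xi]], M * J), nrow = J)
      ll <- matrix(0, nrow = J, ncol = nd)
      for (yi in seq_len(nd)) {
        lv <- .dist_log_density_grid(dists[[yi]], as.vector(x))
        ll[, yi] <- rowSums(matrix(lv, nrow = J))
      }
      ll[is.nan(ll)] <- -Inf     # block all outside support for a candidate
      true_ll <- ll[, xi]
      other <- ll[, -xi, drop = FALSE]
      wrong <- apply(other, 1, max) >= true_ll
      err <- err + mean(wrong)
    }
    100 * err / nd
  })
}

.check_dists <- function(dists) {
  if (inherits(dists, "current_distribution")) dists <- list(dists)
  stopifnot(is.list(dists), length(dists) >= 2)
  for (d in dists) {
    if (!inherits(d, "current_distribution")) {
      stop("dists must be current_distribution objects")
    }
    if (isTRUE(d$point_mass)) {
      stop("point-mass distribution has empty density support")
    }
    if (d$support[1] >= d$support[2]) stop("distribution with empty support")
  }
  if (is.null(names(dists))) {
    names(dists) <- vapply(dists, `[[`, "", "residue_code")
  }
  dists
}

#' Error curve over measurements-per-residue
#'
#' Runs [ml_error()] for each M in `M_values`.
#'
#' @param dists List of `current_distribution` objects.
#' @param M_values Measurement counts (default 1 and 5, 10, ..., 200).
#' @param J Realizations per residue per M.
#' @param seed Integer seed; each M uses a derived sub-seed.
#' @return `data.frame` of class `error_curve` with columns `M`,
#'   `error_pct`, plus attributes `J` and `seed`.
#' @export
error_curve <- function(dists, M_values = c(1, seq(5, 200, by = 5)),
                        J = 1000, seed = 1L) {
  stopifnot(all(M_values >= 1))
  err <- vapply(seq_along(M_values), function(i) {
    ml_error(dists, M = M_values[i], J = J, seed = seed + i)
  }, numeric(1))
  out <- data.frame(M = M_values, error_pct = err)
  attr(out, "J") <- J
  attr(out, "seed") <- seed
  class(out) <- c("error_curve", "data.frame")
  out
}

#' Sequencing-protocol throughput report
#'
#' Deterministic arithmetic linking the current measurement frequency, the
#' measurements per residue M, and the residue spacing along the chain:
#' `residues_per_second = floor(frequency / M)` and
#' `max_pull_speed = residue_length * frequency / M` (nm/s).
#'
#' @param frequency Measurement frequency, Hz.
#' @param M Measurements per residue.
#' @param residue_length Residue spacing along the chain, Angstrom
#'   (default 3.8).
#' @return Object of class `protocol_report` with fields
#'   `measurement_frequency`, `M`, `residues_per_second`,
#'   `max_pull_speed_nm_s`, `residue_length_A`.
#' @export
protocol_report <- function(frequency, M, residue_length = 3.8) {
  stopifnot(is.finite(frequency), frequency > 0, is.finite(residue_length),
            residue_length > 0)
  if (!is.finite(M) || M <= 0) stop("M must be a positive count")
  structure(
    list(measurement_frequency = frequency, M = M,
         residues_per_second = floor(frequency / M),
         max_pull_speed_nm_s = residue_length * 0.1 * frequency / M,
         residue_length_A = residue_length),
    class = "protocol_report"
  )
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf(
    "<protocol_report: %.0f Hz, M = %d -> %d residues/s, max pull %.1f nm/s>\n",
    x$measurement_frequency, x$M, x$residues_per_second,
    x$max_pull_speed_nm_s))
  invisible(x)
}

#' Decode a current stream into a residue sequence
#'
#' Splits the stream into consecutive blocks of M measurements (residue
#' boundaries assumed known) and makes the maximum-likelihood call per
#' block. A likelihood tie is flagged ambiguous (the first of the tied
#' candidates is reported).
#'
#' @param stream Numeric currents (nA); length must be divisible by M.
#' @param dists List of `current_distribution` objects.
#' @param M Measurements per residue.
#' @return `data.frame` with columns `call` (residue code), `ambiguous`,
#'   and `margin` (log-likelihood gap to the runner-up; `Inf` when all
#'   other candidates are impossible). Zero rows for an empty stream.
#' @export
decode_sequence <- function(stream, dists, M) {
  dists <- .check_dists(dists)
  stopifnot(M >= 1)
  if (length(stream) == 0) {
    return(data.frame(call = character(0), ambiguous = logical(0),
                      margin = numeric(0)))
  }
  if (length(stream) %% M != 0) {
    stop("stream length ", length(stream), " is not divisible by M = ", M)
  }
  nblock <- length(stream) / M
  x <- matrix(stream, nrow = nblock, byrow = TRUE)
  nd <- length(dists)
  ll <- matrix(0, nrow = nblock, ncol = nd)
  for (yi in seq_len(nd)) {
    lv <- .dist_log_density_grid(dists[[yi]], as.vector(t(x)))
    ll[, yi] <- rowSums(matrix(lv, nrow = nblock, byrow = TRUE))
  }
  best <- apply(ll, 1, which.max)
  call <- names(dists)[best]
  best_ll <- ll[cbind(seq_len(nblock), best)]
  second <- vapply(seq_len(nblock), function(i) {
    max(ll[i, -best[i]])
  }, numeric(1))
  ambiguous <- second == best_ll
  margin <- best_ll - second
  margin[best_ll == -Inf] <- -Inf
  data.frame(call = call, ambiguous = ambiguous, margin = margin,
             stringsAsFactors = FALSE)
}
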