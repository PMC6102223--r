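#' Droplet encapsulation design
#'
#' Bundles the physical parameters that determine the mean number of cells
#' per droplet when cells are loaded at random into monodisperse droplets:
#' the loaded cell concentration, the droplet volume, and the on-chip
#' aqueous dilution factor (e.g. 0.5 when the stimulus stream has the same
#' flow rate as the cell stream, so cells are loaded at twice the desired
#' final concentration).
#'
#' @param cell_concentration Loaded cell concentration, cells per mL (>= 0).
#' @param droplet_volume Droplet volume in picoliters (> 0).
#' @param dilution_factor Dimensionless on-chip dilution in (0, 1];
#'   default 1 (no co-flow dilution).
#' @return An object of class `droplet_design`.
#' @examples
#' d <- droplet_design(2.6e6, 92, dilution_factor = 0.5)
#' mean_occupancy(d)  # ~0.12 cells per droplet
#' @export
droplet_design <- function(cell_concentration, droplet_volume,
                           dilution_factor = 1) {
  .check_number(cell_concentration, "cell_concentration", lower = 0)
  .check_number(droplet_volume, "droplet_volume", lower = 0,
                allow_lower = FALSE)
  .check_number(dilution_factor, "dilution_factor", lower = 0, upper = 1,
                allow_lower = FALSE)
  structure(list(cell_concentration = cell_concentration,
                 droplet_volume = droplet_volume,
                 dilution_factor = dilution_factor),
            class = "droplet_design")
}

#' @export
print.droplet_design <- function(x, ...) {
  cat("Droplet encapsulation design\n")
  cat(sprintf("  cell concentration: %g cells/mL (loaded)\n",
              x$cell_concentration))
  cat(sprintf("  droplet volume:     %g pL\n", x$droplet_volume))
  cat(sprintf("  dilution factor:    %g\n", x$dilution_factor))
  cat(sprintf("  mean occupancy:     %.4g cells/droplet\n",
              mean_occupancy(x)))
  invisible(x)
}

#' Mean cells per droplet
#'
#' Expected (Poisson) mean occupancy lambda = concentration x dilution x
#' volume, with picoliter-to-milliliter conversion (1 pL = 1e-9 mL).
#'
#' @param design A [droplet_design()] object.
#' @return Mean cells per droplet (lambda >= 0).
#' @export
mean_occupancy <- function(design) {
  if (!inherits(design, "droplet_design"))
    .stopf("'design' must be a droplet_design object")
  design$cell_concentration * design$dilution_factor *
    design$droplet_volume * 1e-9
}

#' Poisson droplet occupancy distribution
#'
#' Probability that a droplet contains k = 0, ..., `k_max` cells under
#' random encapsulation at mean occupancy `lambda`. The mass beyond
#' `k_max` is attached as attribute `"tail_mass"`.
#'
#' @param lambda Mean cells per droplet (>= 0).
#' @param k_max Largest occupancy reported (>= 0).
#' @return Numeric vector of length `k_max + 1`, named "0" ... "k_max",
#'   with attribute `tail_mass` = P(K > k_max).
#' @export
occupancy_pmf <- function(lambda, k_max = 10L) {
  .check_number(lambda, "lambda", lower = 0)
  k_max <- .check_count(k_max, "k_max")
  p <- stats::dpois(0:k_max, lambda)
  names(p) <- as.character(0:k_max)
  attr(p, "tail_mass") <- stats::ppois(k_max, lambda, lower.tail = FALSE)
  p
}

#' Fraction of droplets containing at least one cell
#'
#' @param lambda Mean cells per droplet (>= 0).
#' @return 1 - exp(-lambda), in \[0, 1).
#' @export
occupied_fraction <- function(lambda) {
  .check_number(lambda, "lambda", lower = 0)
  -expm1(-lambda)
}

#' Single-cell purity
#'
#' Among droplets that contain at least one cell, the fraction containing
#' exactly one: lambda e^(-lambda) / (1 - e^(-lambda)). Decreasing in
#' lambda, with limit 1 as lambda -> 0 (the function is undefined at
#' lambda = 0 itself).
#'
#' @param lambda Mean cells per droplet (> 0).
#' @return P(exactly 1 cell | >= 1 cell), in (0, 1).
#' @examples
#' # at 6% occupied droplets, ~97% of cell-containing droplets are singlets
#' single_cell_purity(calibrate_lambda(0.06))
#' @export
single_cell_purity <- function(lambda) {
  .check_number(lambda, "lambda", lower = 0, allow_lower = FALSE)
  lambda * exp(-lambda) / (-expm1(-lambda))
}

#' Calibrate mean occupancy from a measured occupied fraction
#'
#' Inverts [occupied_fraction()]: lambda = -ln(1 - f). Useful because the
#' measured fraction of cell-containing droplets can sit below the value
#' predicted from the nominal loading concentration (cell loss and
#' settling during encapsulation are not modelled); calibration never
#' assumes the two agree.
#'
#' @param occupied_fraction Measured fraction of droplets with >= 1 cell,
#'   strictly in (0, 1).
#' @return Calibrated lambda (> 0).
#' @export
calibrate_lambda <- function(occupied_fraction) {
  .check_number(occupied_fraction, "occupied_fraction", lower = 0, upper = 1,
                allow_lower = FALSE, allow_upper = FALSE)
  -log1p(-occupied_fraction)
}

#' Sample per-droplet cell counts
#'
#' Independent Poisson(`lambda`) draws, one per droplet. Optionally applies
#' lognormal droplet-volume jitter (coefficient of variation `volume_cv`),
#' which is off by default: monodisperse emulsions are the intended regime.
#'
#' @param lambda Mean cells per droplet (>= 0).
#' @param n_droplets Number of droplets (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @param volume_cv Coefficient of variation of droplet volume (default 0 =
#'   fixed volume). When positive, each droplet's effective lambda is scaled
#'   by a lognormal factor with mean 1.
#' @return Integer vector of per-droplet cell counts.
#' @export
sample_droplet_counts <- function(lambda, n_droplets, seed = NULL,
                                  volume_cv = 0) {
  .check_number(lambda, "lambda", lower = 0)
  n_droplets <- .check_count(n_droplets, "n_droplets")
  .check_number(volume_cv, "volume_cv", lower = 0)
  .set_seed(seed)
  if (n_droplets == 0L) return(integer(0))
  lam <- rep(lambda, n_droplets)
  if (volume_cv > 0) {
    sdlog <- sqrt(log1p(volume_cv^2))
    lam <- lam * stats::rlnorm(n_droplets, meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
  }
  stats::rpois(n_droplets, lam)
}
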