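#' Configuration of the synthetic-data generators
#'
#' One seeded configuration object drives every generator, so that a given
#' config reproduces its datasets byte-identically. Defaults emulate the
#' designs of the droplet experiments the package models: ~6% occupied
#' droplets, a dose titration of a TLR9 ligand with a dose-flat IFN-alpha
#' branch and graded NF-kB-branch markers, a 24-point co-encapsulation
#' series generated under an early-responder truth, a conditioned-medium
#' priming titration, and UMI count matrices with known true molecule
#' counts.
#'
#' The co-encapsulation series carries its own truth: a singleton
#' early-responder fraction `coencap_e_true` (percent, default 1.5) and a
#' large in-droplet priming multiplier `coencap_pi_true` (default 500,
#' i.e. a co-encapsulated partner of an early responder is induced almost
#' surely within the incubation), independent of the illustrative global
#' `params`.
#'
#' @param seed Integer seed.
#' @param n_droplets Droplets sampled per occupancy experiment.
#' @param lambda Mean occupancy; default calibrated to 6% occupied droplets.
#' @param params An [activation_params()] object.
#' @param dose_grid TLR ligand doses (ug/mL) of the titration.
#' @param cells_per_condition Cells measured per condition.
#' @param cm_fraction_grid Conditioned-medium percentages of the priming
#'   titration.
#' @param cm_half_saturation CM percentage at half-maximal priming.
#' @param coencap_p_grid Target percentages of multi-cell droplets
#'   (24 points by default).
#' @param coencap_droplets Occupied droplets measured per co-encapsulation
#'   record.
#' @param coencap_e_true True early-responder (singleton) percentage of the
#'   co-encapsulation series.
#' @param coencap_pi_true In-droplet priming multiplier of the
#'   co-encapsulation truth.
#' @param umi List with `n_genes`, `n_cells`, `mean_depth` (mean true
#'   molecules per cell), `dispersion` (negative-binomial dispersion) and
#'   `umi_space`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_droplets = 10000L,
                             lambda = calibrate_lambda(0.06),
                             params = activation_params(),
                             dose_grid = c(0.05, 0.5, 5, 50),
                             cells_per_condition = 5000L,
                             cm_fraction_grid = c(0, 1, 3, 10, 30),
                             cm_half_saturation = 5,
                             coencap_p_grid = seq(2.5, 60, by = 2.5),
                             coencap_droplets = 2000L,
                             coencap_e_true = 1.5,
                             coencap_pi_true = 500,
                             umi = list(n_genes = 150L, n_cells = 60L,
                                        mean_depth = 4677,
                                        dispersion = 0.5,
                                        umi_space = 4096L)) {
  seed <- .check_count(seed, "seed")
  n_droplets <- .check_count(n_droplets, "n_droplets")
  .check_number(lambda, "lambda", lower = 0)
  stopifnot(inherits(params, "activation_params"))
  if (any(!is.finite(dose_grid)) || any(dose_grid < 0))
    .stopf("'dose_grid' must be finite and nonnegative")
  cells_per_condition <- .check_count(cells_per_condition,
                                      "cells_per_condition")
  if (any(!is.finite(cm_fraction_grid)) || any(cm_fraction_grid < 0))
    .stopf("'cm_fraction_grid' must be finite and nonnegative")
  .check_number(cm_half_saturation, "cm_half_saturation", lower = 0,
                allow_lower = FALSE)
  if (any(!is.finite(coencap_p_grid)) || any(coencap_p_grid < 0) ||
      any(coencap_p_grid > 100))
    .stopf("'coencap_p_grid' must lie in [0, 100]")
  coencap_droplets <- .check_count(coencap_droplets, "coencap_droplets")
  .check_number(coencap_e_true, "coencap_e_true", lower = 0, upper = 100)
  .check_number(coencap_pi_true, "coencap_pi_true", lower = 1)
  stopifnot(is.list(umi),
            all(c("n_genes", "n_cells", "mean_depth", "dispersion",
                  "umi_space") %in% names(umi)))
  structure(list(seed = seed, n_droplets = n_droplets, lambda = lambda,
                 params = params, dose_grid = dose_grid,
                 cells_per_condition = cells_per_condition,
                 cm_fraction_grid = cm_fraction_grid,
                 cm_half_saturation = cm_half_saturation,
                 coencap_p_grid = coencap_p_grid,
                 coencap_droplets = coencap_droplets,
                 coencap_e_true = coencap_e_true,
                 coencap_pi_true = coencap_pi_true,
                 umi = umi),
            class = "generator_config")
}

#' Generate a dose-response series of marker-positive fractions
#'
#' For each dose of the grid, simulates individually encapsulated cells
#' under TLR stimulation and tabulates the fraction positive for each
#' readout. The IFN-alpha branch is digital (flat across positive doses);
#' TNF-alpha, CCR7, CD40, CD86 and viability follow graded Hill curves.
#' Counting noise is binomial at the per-condition cell number.
#'
#' @param config A [generator_config()].
#' @return A tidy data frame with columns `dose`, `marker`,
#'   `fraction_positive` and `n`.
#' @export
generate_dose_series <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  markers <- c("ifn", "tnf", "ccr7", "cd40", "cd86", "viable")
  cols <- c("ifn_pos", "tnf_pos", "ccr7_pos", "cd40_pos", "cd86_pos",
            "viable")
  out <- lapply(config$dose_grid, function(dose) {
    sim <- simulate_single_cells(config$params,
                                 stimulus_condition("TLR", dose = dose),
                                 config$cells_per_condition)
    data.frame(dose = dose, marker = markers,
               fraction_positive = vapply(cols, function(cl) mean(sim[[cl]]),
                                          numeric(1)),
               n = config$cells_per_condition, row.names = NULL)
  })
  do.call(rbind, out)
}

# multi-cell fraction among occupied droplets for a zero-truncated
# Poisson(lambda) occupancy
.ztp_multi_fraction <- function(lambda) {
  occ <- -expm1(-lambda)
  (occ - lambda * exp(-lambda)) / occ
}

# lambda whose zero-truncated Poisson yields the target multi-cell
# percentage among occupied droplets
.lambda_for_p_multi <- function(p_multi) {
  if (p_multi <= 0) return(0)
  stats::uniroot(function(l) .ztp_multi_fraction(l) - p_multi / 100,
                 interval = c(1e-8, 50), tol = 1e-10)$root
}

#' Generate a co-encapsulation series under an early-responder truth
#'
#' Produces a paired series of (percent multi-cell droplets, percent
#' IFN-alpha-positive cells) records under an early-responder truth with
#' binomial counting noise. Two generating mechanisms:
#' \describe{
#'   \item{`"model"` (default)}{each record's positive-cell count is a
#'     binomial draw around the early-responder interaction curve
#'     `y = e (1 + p/100)` (the fraction of cells measured per record is
#'     `coencap_droplets x (1 + p/100)` cells, i.e. the collapsed-pair
#'     bookkeeping of the model itself);}
#'   \item{`"cohort"`}{per-droplet counts are drawn from a Poisson
#'     occupancy whose multi-cell fraction (after discarding empties)
#'     matches the target, and outcomes come from
#'     [simulate_droplet_cohort()] in `"early_responder"` mode with
#'     singleton fraction `coencap_e_true` and priming multiplier
#'     `coencap_pi_true`. Note that the cell-level first-passage mechanism
#'     produces a steeper population curve than the droplet-level
#'     bookkeeping of the early-responder regression model, so the two
#'     mechanisms are not interchangeable for model-comparison studies.}
#' }
#' In both cases the realised multi-cell percentage (multiplets collapsed
#' to pairs) is recorded alongside the observed positive percentage.
#'
#' @param config A [generator_config()].
#' @param mechanism `"model"` or `"cohort"`, see Details.
#' @return A [coencap_dataset()] (24 records with the default grid).
#' @export
generate_coencap_series <- function(config, mechanism = c("model", "cohort")) {
  stopifnot(inherits(config, "generator_config"))
  mechanism <- match.arg(mechanism)
  set.seed(config$seed)
  e <- config$coencap_e_true
  if (mechanism == "model") {
    p <- config$coencap_p_grid
    n_cells <- round(config$coencap_droplets * (1 + p / 100))
    y <- 100 * stats::rbinom(length(p), n_cells, e / 100 * (1 + p / 100)) /
      n_cells
    return(coencap_dataset(p, y))
  }
  condition <- stimulus_condition("TLR", dose = 50)
  T <- condition$incubation_time
  a_tlr <- -log1p(-e / 100) / T
  truth <- activation_params(a0 = a_tlr / 20, fold_tlr = 20,
                             priming_multiplier = config$coencap_pi_true)
  rec <- lapply(config$coencap_p_grid, function(p_target) {
    lambda <- .lambda_for_p_multi(p_target)
    if (lambda == 0) {
      occ <- rep(1L, config$coencap_droplets)   # pure singleton series
    } else {
      counts <- integer(0)
      while (sum(counts > 0) < config$coencap_droplets) {
        need <- config$coencap_droplets - sum(counts > 0)
        extra <- stats::rpois(ceiling(need / -expm1(-lambda)) + 10, lambda)
        counts <- c(counts, extra)
      }
      occ <- counts[counts > 0]
      occ <- occ[seq_len(config$coencap_droplets)]
    }
    sim <- simulate_droplet_cohort(truth, condition, occ,
                                   mode = "early_responder")
    c(p_multi = collapse_multiplets(occ), y = 100 * mean(sim$ifn_pos))
  })
  rec <- do.call(rbind, rec)
  coencap_dataset(rec[, "p_multi"], rec[, "y"])
}

#' Generate a conditioned-medium priming titration
#'
#' The effective priming multiplier follows a saturating function of the
#' conditioned-medium percentage,
#' `pi(cm) = 1 + (pi - 1) cm / (cm + cm_half_saturation)`, so the
#' IFN-alpha-positive fraction rises and saturates with CM while staying
#' independent of the TLR ligand dose at fixed priming.
#'
#' @param config A [generator_config()].
#' @return Data frame with columns `cm_fraction`, `fraction_ifn`, `n`.
#' @export
generate_priming_series <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  p <- config$params
  out <- lapply(config$cm_fraction_grid, function(cm) {
    pi_eff <- 1 + (p$priming_multiplier - 1) *
      cm / (cm + config$cm_half_saturation)
    params_cm <- p
    params_cm$priming_multiplier <- max(1, pi_eff)
    cond <- stimulus_condition("TLR", dose = 50,
                               primed_externally = cm > 0)
    sim <- simulate_single_cells(params_cm, cond, config$cells_per_condition)
    data.frame(cm_fraction = cm, fraction_ifn = mean(sim$ifn_pos),
               n = config$cells_per_condition)
  })
  do.call(rbind, out)
}

#' Generate a UMI count matrix with known ground truth
#'
#' True molecule counts per gene and cell are drawn negative-binomially
#' (lognormal gene means, lognormal cell size factors, scaled so the mean
#' per-cell depth matches `umi$mean_depth`); observed distinct-UMI counts
#' are produced by throwing each entry's molecules into `umi$umi_space`
#' random barcodes and counting occupied ones, i.e. by simulating the
#' forward collision process that [correct_umi_count()] inverts. UMI
#' spaces of 1e8 or more are treated as collision-free (observed equals
#' truth), the exact limit of the process.
#'
#' @param config A [generator_config()].
#' @return List with integer matrices `observed` and `truth` (genes x
#'   cells, dimnames set) and `umi_space`.
#' @export
generate_umi_matrix <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  u <- config$umi
  ng <- .check_count(u$n_genes, "umi$n_genes")
  nc <- .check_count(u$n_cells, "umi$n_cells")
  K <- u$umi_space
  gene_mu <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.2)
  cell_sf <- stats::rlnorm(nc, meanlog = -0.3^2 / 2, sdlog = 0.3)
  mu <- outer(gene_mu, cell_sf)
  mu <- mu * u$mean_depth / mean(colSums(mu))
  size <- 1 / u$dispersion
  truth <- matrix(stats::rnbinom(ng * nc, mu = as.vector(mu), size = size),
                  nrow = ng)
  storage.mode(truth) <- "integer"
  observed <- truth
  pos <- which(truth > 0)
  observed[pos] <- vapply(truth[pos], function(m) {
    if (K >= 1e8) m else length(unique(sample.int(K, m, replace = TRUE)))
  }, integer(1))
  dn <- list(paste0("gene", seq_len(ng)), paste0("cell", seq_len(nc)))
  dimnames(truth) <- dn
  dimnames(observed) <- dn
  list(observed = observed, truth = truth, umi_space = K)
}
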