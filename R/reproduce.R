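#' Run the end-to-end synthetic reproduction pipeline
#'
#' Executes the whole pipeline on synthetic data — occupancy statistics,
#' dose-response generation, co-encapsulation model comparison,
#' fold-change recovery and UMI-correction round trip — and assembles a
#' report. Every section is seeded through the configuration, so the same
#' seed regenerates the report byte-identically.
#'
#' Report sections:
#' \describe{
#'   \item{occupancy}{mean occupancy calibrated to a 6% occupied-droplet
#'     fraction, the closed-form single-cell purity at that occupancy, and
#'     a chi-square goodness-of-fit p-value of sampled droplet counts
#'     against the Poisson occupancy distribution;}
#'   \item{dose_response}{weighted regression slope (and p-value) of the
#'     IFN-alpha-positive fraction on log10 dose — flat for the digital
#'     IFN branch — and the rank correlation of the TNF-alpha fraction
#'     with dose;}
#'   \item{coencap}{mean train/test RMSE of the random-pair (A) and
#'     early-responder (B) models on the generated 24-point series and
#'     the fitted early-responder fraction;}
#'   \item{fold_change}{hazard fold recovered from two simulated arms and
#'     the configured truth;}
#'   \item{umi}{mean and maximum relative error of collision-corrected
#'     per-cell totals against the true molecule totals.}
#' }
#'
#' @param seed Integer seed (used for the default config and all
#'   downstream randomness).
#' @param config A [generator_config()]; defaults to
#'   `generator_config(seed = seed)`.
#' @param out_dir Optional directory; when given, `report.json` and
#'   `report.txt` are written there, each embedding the package version,
#'   the configuration hash and the seed.
#' @param overwrite Overwrite existing report files (default FALSE).
#' @param n_cells_fold Cells per arm for the fold-recovery section
#'   (default 1e5).
#' @return An object of class `pdcsim_report` (a nested list), invisibly
#'   when `out_dir` is given.
#' @export
run_reproduction <- function(seed = 1L, config = generator_config(seed = seed),
                             out_dir = NULL, overwrite = FALSE,
                             n_cells_fold = 1e5) {
  stopifnot(inherits(config, "generator_config"))
  n_cells_fold <- .check_count(n_cells_fold, "n_cells_fold", lower = 1)
  .check_flag(overwrite, "overwrite")

  # occupancy: calibrated purity + sampled-histogram goodness of fit
  lam <- calibrate_lambda(0.06)
  purity_pct <- 100 * single_cell_purity(lam)
  set.seed(config$seed)
  draws <- sample_droplet_counts(config$lambda, config$n_droplets)
  k_top <- max(3L, max(draws))
  obs <- tabulate(draws + 1L, nbins = k_top + 1L)
  probs <- stats::dpois(0:(k_top - 1L), config$lambda)
  probs <- c(probs, 1 - sum(probs))              # pooled tail bin
  obs <- c(obs[seq_len(k_top)], sum(obs[-seq_len(k_top)]))
  keep <- probs * config$n_droplets >= 1         # drop near-empty bins
  chisq_p <- stats::chisq.test(obs[keep], p = probs[keep],
                               rescale.p = TRUE)$p.value
  occupancy <- list(lambda_calibrated = lam,
                    single_cell_purity_pct = purity_pct,
                    chisq_gof_p = chisq_p)

  # dose response: IFN branch flat, TNF branch graded
  dose <- generate_dose_series(config)
  ifn <- dose[dose$marker == "ifn", ]
  fit <- stats::lm(fraction_positive ~ log10(dose), data = ifn,
                   weights = ifn$n)
  sl <- summary(fit)$coefficients
  tnf <- dose[dose$marker == "tnf", ]
  dose_response <- list(
    ifn_slope_per_log10_dose = unname(sl["log10(dose)", "Estimate"]),
    ifn_slope_p = unname(sl["log10(dose)", "Pr(>|t|)"]),
    ifn_flat = unname(sl["log10(dose)", "Pr(>|t|)"]) > 0.05,
    tnf_dose_spearman = suppressWarnings(
      stats::cor(tnf$dose, tnf$fraction_positive, method = "spearman")))

  # co-encapsulation model comparison
  ds <- generate_coencap_series(config)
  cv <- compare_models(ds, n_repeats = 100, split = 0.75, seed = config$seed)
  fb <- coencap_fit(ds, "early_responder")
  coencap <- list(rmse_A = cv$rmse_A, rmse_B = cv$rmse_B,
                  preferred = if (cv$rmse_B < cv$rmse_A) "early_responder"
                              else "random_pair",
                  fitted_e_pct = unname(coef(fb)),
                  true_e_pct = config$coencap_e_true)

  # fold-change recovery from two simulated arms
  set.seed(config$seed + 1L)
  cond_un <- stimulus_condition("IL3")
  cond_tlr <- stimulus_condition("TLR", dose = 50)
  f_un <- mean(simulate_single_cells(config$params, cond_un,
                                     n_cells_fold)$ifn_pos)
  f_tlr <- mean(simulate_single_cells(config$params, cond_tlr,
                                      n_cells_fold)$ifn_pos)
  fold_change <- list(frac_unstim = f_un, frac_tlr = f_tlr,
                      recovered_fold = fit_fold_change(f_un, f_tlr),
                      true_fold = config$params$fold_tlr,
                      n_per_arm = n_cells_fold)

  # UMI collision-correction round trip
  gm <- generate_umi_matrix(config)
  corrected <- correct_umi_matrix(gm$observed, gm$umi_space)
  truth_tot <- colSums(gm$truth)
  rel_err <- abs(colSums(corrected) - truth_tot) /
    pmax(truth_tot, .Machine$double.eps)
  umi <- list(mean_rel_error = mean(rel_err), max_rel_error = max(rel_err),
              umi_space = gm$umi_space)

  report <- structure(
    list(package_version = as.character(utils::packageVersion("pdcsim")),
         seed = config$seed,
         config_hash = .config_hash(unclass(config)),
         occupancy = occupancy,
         dose_response = dose_response,
         coencap = coencap,
         fold_change = fold_change,
         umi = umi),
    class = "pdcsim_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    json_path <- file.path(out_dir, "report.json")
    txt_path <- file.path(out_dir, "report.txt")
    if (!overwrite && (file.exists(json_path) || file.exists(txt_path)))
      .stopf("report files already exist in '%s'; set overwrite = TRUE",
             out_dir)
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(utils::capture.output(print(report)), txt_path)
    return(invisible(report))
  }
  report
}

#' @export
print.pdcsim_report <- function(x, ...) {
  cat("pdcsim reproduction report\n")
  cat(sprintf("  package %s | seed %d | config %s\n\n",
              x$package_version, x$seed, x$config_hash))
  cat("Occupancy (calibrated to 6% occupied droplets)\n")
  cat(sprintf("  lambda = %.6f, single-cell purity = %.2f%%\n",
              x$occupancy$lambda_calibrated,
              x$occupancy$single_cell_purity_pct))
  cat(sprintf("  Poisson GOF chi-square p = %.3g\n\n", x$occupancy$chisq_gof_p))
  cat("Dose response\n")
  cat(sprintf("  IFN slope vs log10 dose = %.3g (p = %.3g, flat: %s)\n",
              x$dose_response$ifn_slope_per_log10_dose,
              x$dose_response$ifn_slope_p, x$dose_response$ifn_flat))
  cat(sprintf("  TNF-dose Spearman rho = %.3f\n\n",
              x$dose_response$tnf_dose_spearman))
  cat("Co-encapsulation model comparison (100 x 75/25 splits)\n")
  cat(sprintf("  mean RMSE A (random pair)     = %.4f%%\n", x$coencap$rmse_A))
  cat(sprintf("  mean RMSE B (early responder) = %.4f%%\n", x$coencap$rmse_B))
  cat(sprintf("  preferred: %s; fitted e = %.3f%% (truth %.3f%%)\n\n",
              x$coencap$preferred, x$coencap$fitted_e_pct,
              x$coencap$true_e_pct))
  cat("Fold-change recovery\n")
  cat(sprintf("  fractions %.4f%% (unstim) vs %.2f%% (TLR)\n",
              100 * x$fold_change$frac_unstim, 100 * x$fold_change$frac_tlr))
  cat(sprintf("  recovered fold = %.2f (truth %g, n = %g per arm)\n\n",
              x$fold_change$recovered_fold, x$fold_change$true_fold,
              x$fold_change$n_per_arm))
  cat("UMI correction round trip\n")
  cat(sprintf("  per-cell total relative error: mean %.4f%%, max %.4f%%\n",
              100 * x$umi$mean_rel_error, 100 * x$umi$max_rel_error))
  invisible(x)
}
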