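#' Co-encapsulation dataset
#'
#' Paired observations from a co-encapsulation series: the percentage of
#' (occupied) droplets containing more than one cell and the percentage of
#' cells producing IFN-alpha, optionally labelled by donor.
#'
#' @param p_multi Percent of droplets with > 1 cells, in \[0, 100\].
#' @param y Percent of IFN-alpha-producing cells, in \[0, 100\].
#' @param donor Optional donor labels (recycled).
#' @return A data frame of class `coencap_dataset` with columns `p_multi`,
#'   `y` and (optionally) `donor`.
#' @export
coencap_dataset <- function(p_multi, y, donor = NULL) {
  if (length(p_multi) != length(y))
    .stopf("'p_multi' and 'y' must have the same length")
  if (length(y) < 1L) .stopf("at least one record is required")
  if (any(!is.finite(p_multi)) || any(p_multi < 0) || any(p_multi > 100))
    .stopf("'p_multi' must lie in [0, 100]")
  if (any(!is.finite(y)) || any(y < 0) || any(y > 100))
    .stopf("'y' must lie in [0, 100]")
  out <- data.frame(p_multi = as.numeric(p_multi), y = as.numeric(y))
  if (!is.null(donor)) out$donor <- rep_len(donor, nrow(out))
  class(out) <- c("coencap_dataset", "data.frame")
  out
}

.as_coencap <- function(data) {
  if (inherits(data, "coencap_dataset")) return(data)
  if (is.data.frame(data) && all(c("p_multi", "y") %in% names(data)))
    return(coencap_dataset(data$p_multi, data$y, data$donor))
  .stopf("'data' must be a coencap_dataset or a data frame with columns 'p_multi' and 'y'")
}

#' Random-pair predictor: percent of cells in multi-cell droplets
#'
#' Converts the percentage `p` of droplets with more than one cell
#' (multiplets already collapsed to two cells) into the percentage of
#' cells sitting in multi-cell droplets: `200 p / (100 + p)`. Increasing,
#' concave, and a bijection of \[0, 100\] onto itself;
#' [predictor_random_pair_inverse()] is its inverse.
#'
#' @param p Percent of droplets with > 1 cells, in \[0, 100\] (vectorised).
#' @return Percent of cells in multi-cell droplets, in \[0, 100\].
#' @export
predictor_random_pair <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
    .stopf("'p' must lie in [0, 100]")
  200 * p / (100 + p)
}

#' @rdname predictor_random_pair
#' @param x Percent of cells in multi-cell droplets, in \[0, 100\].
#' @export
predictor_random_pair_inverse <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100))
    .stopf("'x' must lie in [0, 100]")
  100 * x / (200 - x)
}

#' Collapse multiplets and compute the multi-cell droplet percentage
#'
#' Droplets with three or more cells are treated as if they contained only
#' two cells, so the summary is simply the percentage of occupied droplets
#' containing at least two cells. Empty droplets carry no cells and are
#' excluded from the denominator.
#'
#' @param counts Nonnegative integer per-droplet cell counts.
#' @return Percent of occupied droplets with >= 2 cells.
#' @export
collapse_multiplets <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != as.integer(counts)))
    .stopf("'counts' must be nonnegative integers")
  occ <- counts[counts > 0]
  if (length(occ) == 0L) .stopf("no occupied droplets")
  100 * mean(occ >= 2)
}

#' Fit a co-encapsulation interaction model
#'
#' Two competing explanations for the rise of the IFN-alpha-producing cell
#' percentage `y` with the multi-cell droplet percentage `p`:
#' \describe{
#'   \item{`"random_pair"` (model A)}{any two co-encapsulated pDCs induce
#'     each other; `y` is regressed by ordinary least squares on the
#'     percentage of cells in multi-cell droplets,
#'     `x = 200 p / (100 + p)`, with an intercept (set
#'     `intercept = FALSE` for a through-origin variant).}
#'   \item{`"early_responder"` (model B)}{a rare early-responding fraction
#'     `e` (percent) of cells secretes first and induces its droplet
#'     partners, giving `y = e (1 + p / 100)`; `e` is the one-parameter
#'     least-squares solution `sum(y w) / sum(w^2)` with `w = 1 + p/100`,
#'     clamped at zero.}
#' }
#'
#' @param data A [coencap_dataset()] (or data frame with columns `p_multi`
#'   and `y`).
#' @param model `"random_pair"` or `"early_responder"`.
#' @param intercept For the random-pair model only: include an intercept
#'   (default TRUE).
#' @return An object of class `coencap_fit` with methods [print()],
#'   [summary()], [coef()], [predict()], [fitted()], [residuals()],
#'   [plot()] and [simulate()].
#' @examples
#' d <- coencap_dataset(p_multi = c(0, 10, 25, 50),
#'                      y = c(1.6, 1.7, 1.9, 2.2))
#' fit <- coencap_fit(d, "early_responder")
#' coef(fit)
#' predict(fit, data.frame(p_multi = 30))
#' @export
coencap_fit <- function(data, model = c("random_pair", "early_responder"),
                        intercept = TRUE) {
  data <- .as_coencap(data)
  model <- match.arg(model)
  .check_flag(intercept, "intercept")
  p <- data$p_multi
  y <- data$y
  if (model == "random_pair") {
    if (length(y) < 2L)
      .stopf("the random-pair model needs at least 2 records")
    x <- predictor_random_pair(p)
    if (diff(range(x)) == 0)
      .stopf("degenerate design: all predictor values are identical")
    lmfit <- if (intercept) stats::lm(y ~ x, data = data.frame(x = x, y = y))
             else stats::lm(y ~ x - 1, data = data.frame(x = x, y = y))
    cf <- stats::coef(lmfit)
    coefficients <- if (intercept) c(intercept = unname(cf[1]),
                                     slope = unname(cf[2]))
                    else c(slope = unname(cf[1]))
    fitted_vals <- unname(stats::fitted(lmfit))
    lm_obj <- lmfit
  } else {
    w <- 1 + p / 100
    e <- max(0, sum(y * w) / sum(w * w))
    coefficients <- c(early_responder_fraction = e)
    fitted_vals <- e * w
    lm_obj <- NULL
  }
  structure(list(model = model,
                 coefficients = coefficients,
                 data = data,
                 fitted.values = fitted_vals,
                 residuals = y - fitted_vals,
                 intercept = intercept,
                 lm = lm_obj,
                 call = match.call()),
            class = "coencap_fit")
}

#' @export
coef.coencap_fit <- function(object, ...) object$coefficients

#' @export
fitted.coencap_fit <- function(object, ...) object$fitted.values

#' @export
residuals.coencap_fit <- function(object, ...) object$residuals

#' Predict from a fitted co-encapsulation model
#'
#' @param object A [coencap_fit()] object.
#' @param newdata Data frame with a `p_multi` column, or a numeric vector
#'   of multi-cell droplet percentages; `NULL` returns fitted values.
#' @param ... Unused.
#' @return Predicted percentages of IFN-alpha-producing cells.
#' @export
predict.coencap_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  p <- if (is.data.frame(newdata)) newdata$p_multi else newdata
  if (is.null(p)) .stopf("'newdata' must supply 'p_multi'")
  if (object$model == "random_pair") {
    x <- predictor_random_pair(p)
    cf <- object$coefficients
    if (object$intercept) unname(cf["intercept"] + cf["slope"] * x)
    else unname(cf["slope"] * x)
  } else {
    unname(object$coefficients[["early_responder_fraction"]] * (1 + p / 100))
  }
}

#' @export
print.coencap_fit <- function(x, ...) {
  lab <- switch(x$model,
                random_pair = "random-pair interaction (model A)",
                early_responder = "early-responder interaction (model B)")
  cat("Co-encapsulation model:", lab, "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.coencap_fit <- function(object, ...) {
  out <- list(model = object$model,
              coefficients = object$coefficients,
              n = nrow(object$data),
              rmse_train = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.coencap_fit"
  out
}

#' @export
print.summary.coencap_fit <- function(x, ...) {
  cat("Co-encapsulation model fit:", x$model, "\n")
  cat("Records:", x$n, "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("Training RMSE: %.4f%%\n", x$rmse_train))
  invisible(x)
}

#' @export
plot.coencap_fit <- function(x, ...) {
  d <- x$data
  grid <- seq(0, max(100, max(d$p_multi)), length.out = 200)
  grid <- grid[grid <= 100]
  graphics::plot(d$p_multi, d$y,
                 xlab = "% droplets with > 1 cell",
                 ylab = "% IFN-alpha-producing cells", ...)
  graphics::lines(grid, predict(x, grid), col = 2)
  invisible(x)
}

#' @export
simulate.coencap_fit <- function(object, nsim = 1, seed = NULL, ...) {
  .set_seed(seed)
  mu <- object$fitted.values
  sd <- sqrt(mean(object$residuals^2))
  out <- as.data.frame(replicate(nsim, pmax(0, stats::rnorm(length(mu), mu, sd))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Root-mean-square prediction error on a test set
#'
#' @param object A fitted [coencap_fit()] model.
#' @param test A [coencap_dataset()] (nonempty) to predict.
#' @return RMSE in percent IFN-alpha-producing cells; 0 iff prediction is
#'   perfect.
#' @export
rmse <- function(object, test) {
  if (!inherits(object, "coencap_fit")) .stopf("'object' must be a coencap_fit")
  test <- .as_coencap(test)
  if (nrow(test) == 0L) .stopf("empty test set")
  sqrt(mean((test$y - predict(object, test))^2))
}

#' Repeated train/test comparison of the two co-encapsulation models
#'
#' Randomly partitions the dataset into a training and a test part
#' (training size = round-half-up of `split * n`), fits both interaction
#' models on the training part, scores each by RMSE on the held-out part,
#' and averages over `n_repeats` random partitions. Records are first put
#' into a canonical order (sorted by `p_multi`, then `y`) so that the
#' result depends only on the data values and the seed, not on row order.
#'
#' @param data A [coencap_dataset()] with at least 4 records.
#' @param n_repeats Number of random partitions (default 100).
#' @param split Training fraction in (0, 1) (default 0.75).
#' @param seed Optional integer seed.
#' @return An object of class `coencap_cv`: mean `rmse_A` (random pair)
#'   and `rmse_B` (early responder), the per-repeat RMSEs, and the
#'   partition settings.
#' @export
compare_models <- function(data, n_repeats = 100, split = 0.75, seed = NULL) {
  data <- .as_coencap(data)
  n_repeats <- .check_count(n_repeats, "n_repeats", lower = 1)
  .check_number(split, "split", lower = 0, upper = 1,
                allow_lower = FALSE, allow_upper = FALSE)
  n <- nrow(data)
  if (n < 4L) .stopf("at least 4 records are needed for a train/test split")
  n_train <- as.integer(floor(split * n + 0.5))   # round half up
  if (n_train < 2L || n_train >= n)
    .stopf("split %g leaves no usable train/test partition of %d records",
           split, n)
  ord <- order(data$p_multi, data$y)
  data <- data[ord, , drop = FALSE]
  .set_seed(seed)
  per <- matrix(NA_real_, nrow = n_repeats, ncol = 2,
                dimnames = list(NULL, c("rmse_A", "rmse_B")))
  for (r in seq_len(n_repeats)) {
    idx <- sample.int(n, n_train)
    train <- data[idx, , drop = FALSE]
    test <- data[-idx, , drop = FALSE]
    fa <- coencap_fit(train, "random_pair")
    fb <- coencap_fit(train, "early_responder")
    per[r, ] <- c(rmse(fa, test), rmse(fb, test))
  }
  structure(list(rmse_A = mean(per[, "rmse_A"]),
                 rmse_B = mean(per[, "rmse_B"]),
                 per_repeat = as.data.frame(cbind(repeat_id = seq_len(n_repeats),
                                                  per)),
                 n_repeats = n_repeats,
                 split_fraction = split,
                 n_train = n_train,
                 n = n,
                 seed = seed),
            class = "coencap_cv")
}

#' @export
print.coencap_cv <- function(x, ...) {
  cat("Repeated train/test comparison of co-encapsulation models\n")
  cat(sprintf("  %d repeats, %d/%d train/test records\n",
              x$n_repeats, x$n_train, x$n - x$n_train))
  cat(sprintf("  mean RMSE, model A (random pair):     %.4f%%\n", x$rmse_A))
  cat(sprintf("  mean RMSE, model B (early responder): %.4f%%\n", x$rmse_B))
  better <- if (x$rmse_B < x$rmse_A) "early responder (B)"
            else if (x$rmse_A < x$rmse_B) "random pair (A)" else "tie"
  cat("  preferred model:", better, "\n")
  invisible(x)
}
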