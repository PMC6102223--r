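test_that("the random-pair predictor is a concave bijection of [0,100]", {
  expect_equal(predictor_random_pair(0), 0)
  expect_equal(predictor_random_pair(100), 100)
  expect_equal(predictor_random_pair(10), 2000 / 110)
  expect_error(predictor_random_pair(-1), "\\[0, 100\\]")
  expect_error(predictor_random_pair(101), "\\[0, 100\\]")
  p <- seq(0, 100, by = 0.5)
  x <- predictor_random_pair(p)
  expect_true(all(diff(x) > 0))
  expect_true(all(diff(diff(x)) < 0))          # concave
  expect_equal(predictor_random_pair_inverse(x), p, tolerance = 1e-9)
})

test_that("multiplet collapse counts multi-cell droplets among occupied ones", {
  expect_equal(collapse_multiplets(c(1, 1, 1, 1)), 0)
  expect_equal(collapse_multiplets(c(1, 2, 3, 0)), 200 / 3, tolerance = 1e-9)
  expect_equal(collapse_multiplets(c(2, 2)), 100)
  expect_error(collapse_multiplets(c(0, 0)), "occupied")
  expect_error(collapse_multiplets(c(1.5)), "integers")
})

test_that("the random-pair model is ordinary least squares on the pair predictor", {
  p <- c(0, 10, 30, 60)
  x <- predictor_random_pair(p)
  d <- coencap_dataset(p, 1 + 0.1 * x)
  fit <- coencap_fit(d, "random_pair")
  expect_equal(unname(coef(fit)), c(1, 0.1), tolerance = 1e-9)
  expect_lt(abs(sum(residuals(fit) * x)), 1e-8)   # normal-equation orthogonality

  # 4-point noisy case against hand-written normal equations
  y <- c(1.4, 2.3, 2.1, 3.9)
  fit2 <- coencap_fit(coencap_dataset(p, y), "random_pair")
  expect_equal(unname(coef(fit2)), unname(ols_normal_equations(x, y)),
               tolerance = 1e-9)

  expect_error(coencap_fit(coencap_dataset(c(5, 5, 5), c(1, 2, 3)),
                           "random_pair"), "degenerate")
  expect_error(coencap_fit(coencap_dataset(5, 1), "random_pair"),
               "at least 2")

  # through-origin variant
  fit3 <- coencap_fit(coencap_dataset(p, 0.05 * x), "random_pair",
                      intercept = FALSE)
  expect_equal(unname(coef(fit3)), 0.05, tolerance = 1e-9)
})

test_that("the early-responder model has the stated one-parameter solution", {
  p <- c(0, 20, 50, 80)
  e0 <- 1.7
  fit <- coencap_fit(coencap_dataset(p, e0 * (1 + p / 100)),
                     "early_responder")
  expect_equal(unname(coef(fit)), e0, tolerance = 1e-12)
  expect_equal(unname(coef(coencap_fit(coencap_dataset(0, 2),
                                       "early_responder"))), 2)
  # 3-record case against a grid-search oracle
  p3 <- c(5, 25, 60)
  y3 <- c(1.8, 2.4, 2.1)
  e_hat <- unname(coef(coencap_fit(coencap_dataset(p3, y3),
                                   "early_responder")))
  expect_equal(e_hat, grid_search_e(p3, y3, step = 1e-4, upper = 5),
               tolerance = 1e-4)
  # clamped at zero when the least-squares solution would be negative
  neg <- structure(data.frame(p_multi = c(0, 10), y = c(-2, -1)),
                   class = c("coencap_dataset", "data.frame"))
  expect_equal(unname(coef(coencap_fit(neg, "early_responder"))), 0)
})

test_that("fit methods predict, summarise, plot and simulate coherently", {
  d <- coencap_dataset(c(2, 15, 30, 55), c(1.6, 1.75, 2.0, 2.3),
                       donor = c("d1", "d1", "d2", "d2"))
  for (m in c("random_pair", "early_responder")) {
    fit <- coencap_fit(d, m)
    expect_s3_class(fit, "coencap_fit")
    expect_equal(predict(fit), fitted(fit))
    expect_equal(unname(fitted(fit) + residuals(fit)), d$y)
    expect_equal(predict(fit, data.frame(p_multi = d$p_multi)), fitted(fit))
    expect_output(print(fit), "Co-encapsulation model")
    expect_output(print(summary(fit)), "Training RMSE")
  }
  fit <- coencap_fit(d, "early_responder")
  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_identical(dim(s1), c(4L, 2L))
})

test_that("rmse matches hand-computed residual norms", {
  train <- coencap_dataset(0, 2)                 # e = 2 exactly
  fit <- coencap_fit(train, "early_responder")
  perfect <- coencap_dataset(c(0, 50), 2 * (1 + c(0, 50) / 100))
  expect_equal(rmse(fit, perfect), 0)
  shifted <- coencap_dataset(c(0, 100), 2 * (1 + c(0, 100) / 100) + c(3, -4))
  expect_equal(rmse(fit, shifted), sqrt(25 / 2), tolerance = 1e-12)
  const <- coencap_dataset(c(0, 50), 2 * (1 + c(0, 50) / 100) + 1.3)
  expect_equal(rmse(fit, const), 1.3, tolerance = 1e-12)
  expect_error(rmse(fit, coencap_dataset(numeric(0), numeric(0))),
               "at least one")
})

test_that("repeated train/test comparison is seeded, canonical and sized 18/6 at n=24", {
  set.seed(99)
  p <- seq(2.5, 60, by = 2.5)
  y <- 1.5 * (1 + p / 100) + rnorm(24, 0, 0.2)
  y <- pmin(pmax(y, 0), 100)
  d <- coencap_dataset(p, y)
  cv1 <- compare_models(d, n_repeats = 50, seed = 7)
  cv2 <- compare_models(d, n_repeats = 50, seed = 7)
  expect_identical(cv1[c("rmse_A", "rmse_B", "per_repeat")],
                   cv2[c("rmse_A", "rmse_B", "per_repeat")])
  expect_identical(cv1$n_train, 18L)
  # row order must not matter: the canonical sort absorbs it
  shuf <- d[sample(nrow(d)), ]
  cv3 <- compare_models(shuf, n_repeats = 50, seed = 7)
  expect_equal(cv1$rmse_A, cv3$rmse_A)
  expect_equal(cv1$rmse_B, cv3$rmse_B)
  expect_output(print(cv1), "preferred model")
  expect_error(compare_models(coencap_dataset(c(1, 2, 3), c(1, 2, 3))),
               "at least 4")

  # noiseless early-responder data: model B is exact, model A is not
  d0 <- coencap_dataset(p, 1.5 * (1 + p / 100))
  cv0 <- compare_models(d0, n_repeats = 20, seed = 3)
  expect_equal(cv0$rmse_B, 0, tolerance = 1e-10)
  expect_gt(cv0$rmse_A, 0)
})

test_that("the fitted early-responder fraction tracks the singleton closed form", {
  params <- activation_params(a0 = -log1p(-0.015) / 12 / 20, fold_tlr = 20,
                              priming_multiplier = 5)
  cond <- stimulus_condition("TLR", 50)
  singleton <- 100 * p_ifn(params, cond)
  recs <- lapply(c(5, 10, 15), function(p_target) {
    n_pairs <- round(2000 * p_target / 100)
    counts <- c(rep(1L, 2000 - n_pairs), rep(2L, n_pairs))
    sim <- simulate_droplet_cohort(params, cond, counts, "early_responder",
                                   seed = 60 + p_target)
    c(p = collapse_multiplets(counts), y = 100 * mean(sim$ifn_pos),
      n = nrow(sim))
  })
  recs <- do.call(rbind, recs)
  fit <- coencap_fit(coencap_dataset(recs[, "p"], recs[, "y"]),
                     "early_responder")
  se <- 100 * sqrt(0.015 * 0.985 / sum(recs[, "n"]))
  expect_lt(abs(unname(coef(fit)) - singleton), 3 * se)
})
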