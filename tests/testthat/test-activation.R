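test_that("IFN hazard composes multiplicatively and is digital in dose", {
  p <- activation_params(a0 = 0.001, fold_tlr = 20, priming_multiplier = 5)
  unstim <- stimulus_condition("IL3")
  expect_equal(ifn_hazard(p, unstim), 0.001)
  for (dose in c(0.01, 0.5, 50, 1000))
    expect_equal(ifn_hazard(p, stimulus_condition("TLR", dose)), 0.02)
  expect_equal(ifn_hazard(p, stimulus_condition("TLR", 50), primed = TRUE),
               0.1)
  # external priming and the primed flag are the same multiplier, applied once
  expect_equal(ifn_hazard(p, stimulus_condition("TLR", 50,
                                                primed_externally = TRUE)),
               0.1)
  # order independence: factors commute for any admissible parameter set
  set.seed(1)
  for (i in 1:20) {
    q <- activation_params(a0 = runif(1, 0, 0.1),
                           fold_tlr = runif(1, 1, 50),
                           priming_multiplier = runif(1, 1, 20))
    expect_equal(ifn_hazard(q, stimulus_condition("TLR", 1), primed = TRUE),
                 q$a0 * q$fold_tlr * q$priming_multiplier)
  }
})

test_that("positivity probability is exponential first passage", {
  p <- activation_params(a0 = 0.02, fold_tlr = 1)
  expect_equal(p_ifn(p, stimulus_condition("IL3", incubation_time = 1e-12)), 0,
               tolerance = 1e-10)
  expect_equal(p_ifn(p, stimulus_condition("IL3", incubation_time = 12)),
               0.2133721, tolerance = 1e-6)
})

test_that("the hazard-ratio estimator inverts the two-rate model exactly", {
  expect_equal(fit_fold_change(0.1, 0.1), 1)
  expect_equal(fit_fold_change(1 - exp(-0.012), 1 - exp(-0.24)), 20,
               tolerance = 1e-12)
  expect_error(fit_fold_change(0, 0.5), "range")
  expect_error(fit_fold_change(0.1, 1), "range")
  # round trip with the closed form
  p <- activation_params(a0 = 5e-4, fold_tlr = 13)
  f_u <- p_ifn(p, stimulus_condition("IL3"))
  f_t <- p_ifn(p, stimulus_condition("TLR", 5))
  expect_equal(fit_fold_change(f_u, f_t), 13, tolerance = 1e-10)
})

test_that("single-cell simulation matches closed forms and dose structure", {
  params <- activation_params()
  expect_identical(nrow(simulate_single_cells(params,
                                              stimulus_condition("TLR", 50),
                                              0)), 0L)
  s1 <- simulate_single_cells(params, stimulus_condition("TLR", 50), 100,
                              seed = 9)
  s2 <- simulate_single_cells(params, stimulus_condition("TLR", 50), 100,
                              seed = 9)
  expect_identical(s1, s2)
  expect_true(all(is.na(s1$t_activation) == !s1$ifn_pos))
  expect_true(all(s1$t_activation[s1$ifn_pos] <= 12))

  n <- 2e4
  for (cond in list(stimulus_condition("IL3"),
                    stimulus_condition("TLR", 50))) {
    sim <- simulate_single_cells(params, cond, n, seed = 21)
    expected <- p_ifn(params, cond)
    expect_lt(abs(mean(sim$ifn_pos) - expected),
              binom_3se(expected, n) + 1e-9)
  }

  # digital IFN branch vs graded NF-kB branch across a 1000x dose range
  doses <- c(0.05, 0.5, 5, 50)
  sims <- lapply(seq_along(doses), function(i)
    simulate_single_cells(params, stimulus_condition("TLR", doses[i]), n,
                          seed = 100 + i))
  ifn <- vapply(sims, function(s) mean(s$ifn_pos), numeric(1))
  tnf <- vapply(sims, function(s) mean(s$tnf_pos), numeric(1))
  viable <- vapply(sims, function(s) mean(s$viable), numeric(1))
  ref <- p_ifn(params, stimulus_condition("TLR", 1))
  expect_true(all(abs(ifn - ref) < binom_3se(ref, n)))
  expect_true(all(diff(tnf) > 0))
  expect_gt(viable[4], viable[1])
})

test_that("droplet cohorts reduce to singletons and honour neutral priming", {
  params <- activation_params(a0 = 0.001, fold_tlr = 20,
                              priming_multiplier = 10)
  cond <- stimulus_condition("TLR", 50)
  counts <- rep(1L, 5000)
  a <- simulate_droplet_cohort(params, cond, counts, "none", seed = 4)
  b <- simulate_single_cells(params, cond, 5000, seed = 4)
  expect_identical(a$ifn_pos, b$ifn_pos)
  expect_identical(a$t_activation, b$t_activation)

  neutral <- activation_params(a0 = 0.001, fold_tlr = 20,
                               priming_multiplier = 1)
  mixed <- c(rep(1L, 500), rep(2L, 500), rep(3L, 100))
  none <- simulate_droplet_cohort(neutral, cond, mixed, "none", seed = 11)
  er <- simulate_droplet_cohort(neutral, cond, mixed, "early_responder",
                                seed = 11)
  expect_identical(none$ifn_pos, er$ifn_pos)
  expect_identical(none$t_activation, er$t_activation)
  expect_error(simulate_droplet_cohort(params, cond, mixed, "spillover"),
               "arg")
  expect_error(simulate_droplet_cohort(params, cond, c(-1L, 2L), "none"),
               "nonnegative")
})

test_that("pair droplets match the closed-form early-responder oracle", {
  params <- activation_params(a0 = 0.001, fold_tlr = 20,
                              priming_multiplier = 10)
  cond <- stimulus_condition("TLR", 50)
  n_pairs <- 3e4
  sim <- simulate_droplet_cohort(params, cond, rep(2L, n_pairs),
                                 "early_responder", seed = 8)
  frac <- mean(sim$ifn_pos)
  oracle <- pair_early_responder_prob(0.02, 10, 12)
  singleton <- p_ifn(params, cond)
  expect_gt(oracle, singleton)      # priming raises the pair response
  expect_gt(frac, singleton)
  expect_lt(abs(frac - oracle), binom_3se(oracle, 2 * n_pairs))

  # random-pair mode: every pair cell is primed from t = 0
  rp <- simulate_droplet_cohort(params, cond, rep(2L, n_pairs),
                                "random_pair", seed = 12)
  expected_rp <- 1 - exp(-0.02 * 10 * 12)
  expect_lt(abs(mean(rp$ifn_pos) - expected_rp),
            binom_3se(expected_rp, 2 * n_pairs))
  expect_true(all(rp$primed))
})

test_that("bulk culture reduces to singletons without coupling and responds to density", {
  params <- activation_params(a0 = 0.001, fold_tlr = 20,
                              priming_multiplier = 5, coupling_kappa = 0)
  cond <- stimulus_condition("TLR", 50)
  n <- 4000
  bulk <- simulate_bulk(params, cond, density = 1e6, n_cells = n, dt = 0.02,
                        seed = 31)
  expected <- p_ifn(params, cond)
  expect_lt(abs(bulk$fraction_ifn - expected), binom_3se(expected, n))
  expect_true(all(diff(bulk$trajectory$frac_ifn) >= 0))

  coupled <- activation_params(a0 = 0.001, fold_tlr = 20,
                               priming_multiplier = 5, coupling_kappa = 4e-5)
  fr <- vapply(c(0, 2e5, 2e6), function(d)
    simulate_bulk(coupled, cond, density = d, n_cells = n, dt = 0.02,
                  seed = 32)$fraction_ifn, numeric(1))
  expect_gt(fr[3], fr[1] + binom_3se(expected, n))   # density amplification
  expect_gte(fr[3], fr[2])
  expect_lt(abs(fr[1] - expected), binom_3se(expected, n))

  # blocking the type-I-IFN receptor (neutral multiplier) collapses the
  # bulk response onto the individually-encapsulated fraction
  blocked <- activation_params(a0 = 0.001, fold_tlr = 20,
                               priming_multiplier = 1, coupling_kappa = 4e-5)
  fb <- simulate_bulk(blocked, cond, density = 2e6, n_cells = n, dt = 0.02,
                      seed = 33)$fraction_ifn
  expect_lt(abs(fb - expected), binom_3se(expected, n))
})

test_that("bulk fractions are stable under time-step refinement", {
  params <- activation_params(a0 = 0.001, fold_tlr = 20,
                              priming_multiplier = 5, coupling_kappa = 4e-5)
  cond <- stimulus_condition("TLR", 50)
  n <- 4000
  f1 <- simulate_bulk(params, cond, 5e5, n_cells = n, dt = 0.04,
                      seed = 41)$fraction_ifn
  f2 <- simulate_bulk(params, cond, 5e5, n_cells = n, dt = 0.02,
                      seed = 42)$fraction_ifn
  expect_lt(abs(f1 - f2), 3 * sqrt(2 * f2 * (1 - f2) / n))
})

test_that("fold and priming multiplier are recovered from simulated cohorts", {
  params <- activation_params()   # fold 20, priming multiplier 5
  n <- 1e5
  f_u <- mean(simulate_single_cells(params, stimulus_condition("IL3"), n,
                                    seed = 51)$ifn_pos)
  f_t <- mean(simulate_single_cells(params, stimulus_condition("TLR", 50), n,
                                    seed = 52)$ifn_pos)
  fold_hat <- fit_fold_change(f_u, f_t)
  expect_lt(abs(fold_hat - 20) / 20, 0.30)
  f_pr <- mean(simulate_single_cells(params,
                                     stimulus_condition("TLR", 50,
                                                        primed_externally = TRUE),
                                     n, seed = 53)$ifn_pos)
  pi_hat <- fit_fold_change(f_t, f_pr)
  expect_lt(abs(pi_hat - 5) / 5, 0.30)
})
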