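test_that("single-species dynamics reproduce the logistic closed form", {
  traj <- integrate_lv(matrix(-1), N0 = 0.5, t_end = 10)
  closed <- 1 / (1 + exp(-traj$times))
  expect_lt(max(abs(traj$N[, 1] - closed)), 1e-6)
})

test_that("the equilibrium is a fixed point of the integration", {
  f <- draw_feasible(gen_params(n = 10, P = 0.6, C = 0.8, sigma = 0.02,
                                seed = 31))
  traj <- integrate_lv(f$matrix, N0 = f$eq$Nstar, t_end = 20)
  expect_lt(max(abs(traj$N - rep(f$eq$Nstar, each = length(traj$times)))),
            1e-8)
})

test_that("integration from positive states stays non-negative", {
  f <- draw_feasible(gen_params(n = 12, P = 0.3, C = 0.7, sigma = 0.05,
                                seed = 33))
  N0 <- pmax(f$eq$Nstar - 0.3, 0.05)
  traj <- integrate_lv(f$matrix, N0 = N0, t_end = 25)
  expect_true(all(traj$N >= -1e-9))
})

test_that("divergent runs raise a blow-up error", {
  # two obligate mutualists stronger than the blow-up bound grow without
  # limit from above-equilibrium densities
  A <- matrix(c(-1, 2, 2, -1), 2, 2)
  expect_error(integrate_lv(A, N0 = c(2, 2), t_end = 50,
                            blowup_cap = 1e4),
               class = "lvcomm_blowup_error")
})

test_that("pulse construction and its boundary conditions", {
  expect_equal(pulse_perturb(c(2, 2), species = 1, depth = 0.4),
               c(1.6, 2), ignore_attr = TRUE)
  expect_equal(pulse_perturb(c(1, 2), species = 2, depth = 0),
               c(1, 2), ignore_attr = TRUE)
  expect_error(pulse_perturb(c(1, 2), species = 1, depth = 1),
               class = "lvcomm_pulse_error")
  expect_error(pulse_perturb(c(1, 2), species = 3, depth = 0.1),
               class = "lvcomm_shape_error")
})

test_that("return time is 0 unperturbed and matches the logistic crossing", {
  f <- draw_feasible(gen_params(n = 6, P = 0.5, C = 1, sigma = 0.02,
                                seed = 35))
  traj <- integrate_lv(f$matrix, N0 = f$eq$Nstar, t_end = 5)
  expect_equal(return_time(traj, f$eq$Nstar), 0)

  # logistic from 0.6: |N(t) - 1| = eps at t = log(0.4 * 99 / 0.6)
  traj1 <- integrate_lv(matrix(-1), N0 = 0.6, t_end = 8, n_steps = 1600)
  t_exact <- log(0.4 * 99 / 0.6)
  rt <- return_time(traj1, 1, eps = 0.01, species = 1)
  expect_equal(rt, t_exact, tolerance = 8 / 1600 / t_exact * 1.5)
})

test_that("a perturbation along the N* eigendirection decays at rate 1", {
  f <- draw_feasible(gen_params(n = 8, P = 0.7, C = 1, sigma = 0.02,
                                seed = 37))
  dirn <- f$eq$Nstar / sqrt(sum(f$eq$Nstar^2))
  N0 <- f$eq$Nstar - 0.05 * dirn
  traj <- integrate_lv(f$matrix, N0 = N0, t_end = 6)
  # S N* = -N*: the N* direction is the outlier eigendirection, rate 1
  expect_equal(decay_rate(traj, f$eq$Nstar, t_min = 1, t_max = 5), 1,
               tolerance = 0.02)
})

test_that("tail decay converges to |Lambda| as the pulse shrinks", {
  f <- draw_feasible(gen_params(n = 10, P = 0.4, C = 0.7, sigma = 0.05,
                                seed = 39))
  sp <- community_spectrum(community_matrix(f$eq), f$eq$Nstar)
  errs <- vapply(c(0.1, 0.01, 0.001), function(depth) {
    N0 <- pulse_perturb(f$eq$Nstar, species = 1, depth = depth)
    traj <- integrate_lv(f$matrix, N0 = N0, t_end = 11,
                         rtol = 1e-11, atol = 1e-13)
    abs(decay_rate(traj, f$eq$Nstar, t_min = 5, t_max = 11) - abs(sp$Lambda))
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 1e-6)
  expect_lt(errs[3] / abs(sp$Lambda), 0.02)
})

test_that("two-phase fit recovers the rates of decoupled exponentials", {
  # A = -I with r = (5, 1) puts the equilibrium at (5, 1), so S = DA =
  # diag(-5, -1): a fast and a slow decoupled direction
  A <- diag(-1, 2)
  r <- c(5, 1)
  Nstar <- r
  N0 <- Nstar - c(0.05, 5e-4)
  traj <- integrate_lv(A, r = r, N0 = N0, t_end = 8, n_steps = 800)
  rep2 <- recovery_phases(traj, Nstar, Lambda = -1, bulk_center = -5)
  expect_identical(rep2$n_phases, 2L)
  expect_equal(rep2$phase1_rate, 5, tolerance = 0.15)
  expect_equal(rep2$phase2_rate, 1, tolerance = 0.05)

  # a near-pure slow perturbation cannot resolve two phases
  traj1 <- integrate_lv(A, r = r, N0 = Nstar - c(0, 0.05), t_end = 8,
                        n_steps = 800)
  rep1 <- recovery_phases(traj1, Nstar)
  expect_identical(rep1$n_phases, 1L)
  expect_equal(rep1$phase1_rate, rep1$phase2_rate)
  expect_equal(rep1$phase2_rate, 1, tolerance = 0.05)
})

test_that("large mutualistic communities recover faster in phase 1 than phase 2", {
  f <- draw_feasible(gen_params(n = 100, P = 0.8, C = 0.7, sigma = 0.02,
                                seed = 43))
  sp <- community_spectrum(community_matrix(f$eq), f$eq$Nstar)
  N0 <- pulse_perturb(f$eq$Nstar, species = 1, depth = 0.4)
  traj <- integrate_lv(f$matrix, N0 = N0, t_end = 15)
  rep <- recovery_phases(traj, f$eq$Nstar, Lambda = sp$Lambda,
                         bulk_center = sp$bulk_center)
  expect_gt(rep$phase1_rate, rep$phase2_rate)
})

test_that("perturbing 20 of 100 species still yields finite return times", {
  f <- draw_feasible(gen_params(n = 100, P = 0.6, C = 0.7, sigma = 0.02,
                                seed = 47))
  sp <- community_spectrum(community_matrix(f$eq))
  expect_true(sp$Lambda < 0)
  species <- order(f$eq$Nstar, decreasing = TRUE)[1:20]
  N0 <- pulse_perturb(f$eq$Nstar, species = species, depth = 0.4)
  traj <- integrate_lv(f$matrix, N0 = N0, t_end = 25)
  rt <- return_time(traj, f$eq$Nstar, eps = 0.01)
  expect_true(is.finite(rt) && rt > 0)
})
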