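test_that("pure-birth ML matches the closed-form Yule estimate", {
  lam <- 0.2
  p <- sse_params(lam, 0, matrix(0, 1, 1))
  sim <- simulate_mbd_tree(p, n_extant = 200, seed = 5)
  ## mu fixed at zero: par_map frees lambda only
  fit <- musse_ml(sim$tree, sim$states, k = 1, par_map = c(1L, 0L),
                  fixed = c(0, 0))
  n <- 200; Tlen <- sum(sim$tree$edge.length)
  lam_hat <- (n - 2) / Tlen  # crown Yule MLE, survival-conditioned
  expect_true(fit$converged)
  expect_equal(fit$params$lam, lam_hat, tolerance = 1e-4)
  ## inside the closed-form 95% CI
  se <- lam_hat / sqrt(n - 2)
  expect_lt(abs(fit$params$lam - lam), 1.96 * se + 1e-12)
})

test_that("restarting from the optimum does not improve the likelihood", {
  p <- two_state_params()
  sim <- simulate_mbd_tree(p, n_extant = 80, seed = 12)
  fit <- musse_ml(sim$tree, sim$states, k = 2)
  fit2 <- musse_ml(sim$tree, sim$states, k = 2, init = fit$params)
  expect_lt(fit2$loglik - fit$loglik, 1e-3)
  expect_true(fit$converged)
})

test_that("single-observed-state data reduce to constant-rate birth-death", {
  p <- sse_params(c(0.2, 0.2), c(0.05, 0.05), 0.03)
  sim <- simulate_mbd_tree(sse_params(0.2, 0.05, matrix(0, 1, 1)),
                           n_extant = 100, seed = 8)
  states1 <- tip_state_map(setNames(rep(1L, 100), sim$tree$tip.label), 2)
  ## transitions pinned to zero; state-2 rates never touched by data:
  ## fix them too, leaving lam1, mu1 free
  pm <- c(1L, 0L, 2L, 0L, 0L, 0L)
  fx <- c(0, 0.1, 0, 0.1, 0, 0)
  fit2 <- musse_ml(sim$tree, states1, k = 2, par_map = pm, fixed = fx)
  fit1 <- musse_ml(sim$tree, tip_state_map(setNames(rep(1L, 100),
                                                    sim$tree$tip.label), 1),
                   k = 1)
  expect_equal(fit2$params$lam[1], fit1$params$lam[1], tolerance = 1e-3)
  expect_equal(fit2$params$mu[1], fit1$params$mu[1], tolerance = 1e-3)
})

test_that("tying maps are validated", {
  p <- two_state_params()
  sim <- simulate_mbd_tree(p, n_extant = 20, seed = 2)
  expect_error(musse_ml(sim$tree, sim$states, k = 2, par_map = c(1L, 3L)),
               "cover all")
  expect_error(musse_ml(sim$tree, sim$states, k = 2,
                        par_map = c(1L, 3L, 3L, 0L, 0L, 0L)), "gaps")
  expect_error(musse_ml(sim$tree, sim$states, k = 2,
                        par_map = rep(0L, 6)), "no free")
})

test_that("hidden expansion with one regime is the identity", {
  p <- sse_params(c(0.12, 0.22), c(0.03, 0.05),
                  matrix(c(0, 0.04, 0.07, 0), 2, 2, byrow = TRUE))
  sim <- simulate_mbd_tree(p, n_extant = 40, seed = 14)
  hs <- hidden_spec(2, 1)
  ex <- expand_hidden(hs, sim$states, init = p)
  expect_equal(musse_loglik(sim$tree, ex$states, ex$params_template),
               musse_loglik(sim$tree, sim$states, p), tolerance = 1e-12)
})

test_that("expanded tips are ambiguous over their hidden copies", {
  hs <- hidden_spec(3, 2)
  st <- tip_state_map(c(a = 1, b = 3), 3)
  ex <- expand_hidden(hs, st)
  expect_equal(ex$states$a, c(1L, 4L))
  expect_equal(ex$states$b, c(3L, 6L))
  ## tying map is a partition: every full parameter appears exactly once
  expect_silent(reefdiv:::check_par_map(ex$par_map, length(ex$par_map)))
})

test_that("constrained hidden fits never beat the unconstrained likelihood", {
  p <- sse_params(c(0.08, 0.25), c(0.02, 0.02), 0.02)
  sim <- simulate_mbd_tree(p, n_extant = 80, seed = 19)
  exU <- expand_hidden(hidden_spec(2, 2, "unconstrained"), sim$states)
  exC <- expand_hidden(hidden_spec(2, 2, "cid"), sim$states)
  fitU <- musse_ml(sim$tree, exU$states, k = 4, init = exU$params_template,
                   par_map = exU$par_map, fixed = exU$fixed)
  fitC <- musse_ml(sim$tree, exC$states, k = 4, init = exC$params_template,
                   par_map = exC$par_map, fixed = exC$fixed)
  expect_gte(fitU$loglik, fitC$loglik - 1e-4)  # nested models
  expect_gt(length(fitU$free), length(fitC$free))
})

test_that("model choice recovers a genuine observed-state rate split", {
  ## data generated with strongly state-dependent speciation: the
  ## state-dependent (unconstrained) hidden model should beat the
  ## character-independent one by AIC in a clear majority of replicates
  p <- sse_params(c(0.08, 0.28), c(0.02, 0.02), 0.03)
  wins <- 0L
  n_rep <- 12
  for (i in seq_len(n_rep)) {
    sim <- simulate_mbd_tree(p, n_extant = 110, seed = 3000 + i)
    exU <- expand_hidden(hidden_spec(2, 2, "unconstrained"), sim$states)
    exC <- expand_hidden(hidden_spec(2, 2, "cid"), sim$states)
    fitU <- musse_ml(sim$tree, exU$states, k = 4,
                     init = exU$params_template, par_map = exU$par_map,
                     fixed = exU$fixed, restarts = 1)
    fitC <- musse_ml(sim$tree, exC$states, k = 4,
                     init = exC$params_template, par_map = exC$par_map,
                     fixed = exC$fixed, restarts = 1)
    if (AIC(fitU) < AIC(fitC)) wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})
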