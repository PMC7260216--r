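test_that("pure-birth n_extant simulation yields exactly the requested tips", {
  p <- sse_params(0.1, 0, matrix(0, 1, 1))
  out <- simulate_mbd_tree(p, n_extant = 50, seed = 1)
  expect_s3_class(out$tree, "phylo")
  expect_equal(length(out$tree$tip.label), 50)
  ## no death: pruned and full trees are identical
  expect_equal(length(out$full_tree$tip.label), 50)
  expect_equal(sum(out$true_transitions), 0)
  expect_true(ape::is.ultrametric(out$tree, tol = 1e-8))
})

test_that("mean surviving lineage count matches the birth-death expectation", {
  ## E[N(t)] = n0 e^{(lam-mu) t}; stem start, lam=0.2, mu=0.1, t=10 -> e
  p <- sse_params(0.2, 0.1, matrix(0, 1, 1))
  counts <- vapply(seq_len(600), function(i)
    simulate_mbd_tree(p, max_time = 10, seed = 1000 + i,
                      start = "stem")$n_extant, 0L)
  expected <- exp(1)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("neutral two-state dynamics reach symmetric tip-state frequencies", {
  p <- sse_params(c(0.1, 0.1), c(0.1, 0.1), 0.05)
  freq1 <- numeric(0)
  n1 <- n <- 0
  for (i in seq_len(300)) {
    out <- simulate_mbd_tree(p, max_time = 50, seed = 2000 + i)
    if (out$n_extant >= 1 && !is.null(out$states)) {
      st <- vapply(out$states, `[`, 1L, 1)
      n1 <- n1 + sum(st == 1); n <- n + length(st)
    }
  }
  phat <- n1 / n
  ## clustered within trees, so allow a generous Monte-Carlo band
  expect_gt(phat, 0.35)
  expect_lt(phat, 0.65)
})

test_that("same seed reproduces the simulation bit-for-bit", {
  p <- two_state_params()
  a <- simulate_mbd_tree(p, n_extant = 40, seed = 7)
  b <- simulate_mbd_tree(p, n_extant = 40, seed = 7)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$states, b$states)
  expect_identical(a$true_transitions, b$true_transitions)
})

test_that("tree sets derive distinct per-tree seeds and differing topologies", {
  p <- sse_params(0.15, 0, matrix(0, 1, 1))
  set1 <- simulate_tree_set(p, n_extant = 20, n_trees = 3, seed = 11)
  set2 <- simulate_tree_set(p, n_extant = 20, n_trees = 3, seed = 11)
  nwk1 <- vapply(set1, function(s) ape::write.tree(s$tree), "")
  nwk2 <- vapply(set2, function(s) ape::write.tree(s$tree), "")
  expect_identical(nwk1, nwk2)          # determinism of the whole set
  expect_true(all(nwk1 != nwk1[c(2, 3, 1)]))  # trees differ pairwise
  expect_equal(vapply(set1, function(s) length(s$tree$tip.label), 0L),
               rep(20L, 3))
})

test_that("history segments sum to branch lengths and round-trip the counts", {
  p <- sse_params(c(0.25, 0.25), c(0.05, 0.05), 0.08)
  out <- simulate_mbd_tree(p, n_extant = 60, seed = 5)
  h <- out$history
  durs <- vapply(seq_along(h$edge_segments), function(e)
    sum(h$edge_segments[[e]]$duration), 0)
  expect_equal(durs, h$tree$edge.length, tolerance = 1e-9)
  ## total segment time equals total tree length
  expect_equal(sum(durs), sum(h$tree$edge.length), tolerance = 1e-6)
  ## re-scanning the emitted history recovers the recorded counts
  rescan <- attr(count_transitions(h), "total")
  expect_equal(rescan, unname(out$true_transitions + 0))
  expect_true(all(diag(out$true_transitions) == 0))
})

test_that("pruned tip count equals surviving lineages; extinction errors out", {
  p <- sse_params(c(0.2, 0.2), c(0.1, 0.1), 0.02)
  out <- simulate_mbd_tree(p, n_extant = 30, seed = 9)
  expect_equal(out$n_extant, 30)
  expect_equal(length(out$tree$tip.label), 30)
  expect_gt(length(out$full_tree$tip.label), 30)  # extinct tips pruned

  doomed <- sse_params(0.01, 5, matrix(0, 1, 1))
  expect_error(
    simulate_mbd_tree(doomed, n_extant = 10, seed = 1, max_retries = 5),
    class = "reefdiv_clade_died")
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(sse_params(c(0.1, -0.2), c(0, 0), 0.1), "speciation")
  expect_error(sse_params(0.1, c(0, 0), 0.1), "lengths differ")
  expect_error(sse_params(c(0.1, 0.2), c(0, 0),
                          matrix(c(0, -1, 1, 0), 2, 2)), "transition rates")
  p <- two_state_params()
  expect_error(simulate_mbd_tree(p, n_extant = 10, max_time = 5, seed = 1),
               "exactly one")
  expect_error(simulate_mbd_tree(p, seed = 1), "exactly one")
  expect_error(simulate_mbd_tree(p, root_state = 3, n_extant = 10, seed = 1),
               "root_state")
})

test_that("trait generator honours degenerate settings and planted ratios", {
  ## near-noiseless: all rates within 1% of the constant
  sp <- trait_gen_spec(300, rate_fn = function(g, s) rep(0.1, length(g)),
                       noise_shape = 1e6, seed = 3)
  tt <- simulate_trait_table(sp)
  expect_true(all(abs(tt$true_rates - 0.1) < 0.001))

  ## degenerate guild mix
  sp2 <- trait_gen_spec(50, guild_probs = c(0, 0, 0, 0, 0, 1), seed = 4)
  expect_true(all(simulate_trait_table(sp2)$table$trophic == "HD"))

  ## planted HD/GC ratio of 2 recovered by the law of large numbers
  sp3 <- trait_gen_spec(5000, rate_fn = function(g, s)
    ifelse(g == "HD", 0.2, 0.1), noise_shape = 4, seed = 5)
  tt3 <- simulate_trait_table(sp3)
  m <- tapply(tt3$true_rates, tt3$table$trophic, mean)
  expect_equal(unname(m["HD"] / m["GC"]), 2, tolerance = 0.05)

  ## all ten predictor columns present, no missing values
  expect_true(all(c("trophic", "size", "activity", "position", "range",
                    "basin", "abs_lat", "dist_iaa", "sst", "prprod")
                  %in% names(tt3$table)))
  expect_false(anyNA(tt3$table))
  expect_error(simulate_trait_table(
    trait_gen_spec(10, rate_fn = function(g, s) rep(-1, length(g)))),
    "non-positive")
})
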