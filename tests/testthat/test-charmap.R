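test_that("marginal ASR equals brute-force clamp-and-renormalise", {
  p <- sse_params(c(0.15, 0.25), c(0.03, 0.06),
                  matrix(c(0, 0.08, 0.12, 0), 2, 2, byrow = TRUE))
  st5 <- tip_state_map(c(A = 1, B = 2, C = 1, D = 2, E = 1), 2)
  asr <- marginal_asr(fix_five(), st5, p)
  brute <- brute_marginals(fix_five(), st5, p)
  expect_lt(max(abs(unclass(asr)[,] - brute)), 1e-6)

  ## and on a random small instance with an ambiguous tip
  sim <- simulate_mbd_tree(p, n_extant = 5, seed = 9)
  st <- unclass(sim$states)
  st[[1]] <- 1:2
  st <- tip_state_map(st, 2)
  asr2 <- marginal_asr(sim$tree, st, p)
  brute2 <- brute_marginals(sim$tree, st, p)
  expect_lt(max(abs(unclass(asr2)[,] - brute2)), 1e-6)
})

test_that("symmetric problems give a symmetric root marginal", {
  p <- sse_params(c(0.2, 0.2), c(0.05, 0.05), 0.1)
  tr <- fix_quartet()
  st <- tip_state_map(c(A = 1, B = 2, C = 1, D = 2), 2)
  asr <- marginal_asr(tr, st, p)
  root <- length(tr$tip.label) + 1L
  expect_equal(unname(unclass(asr)[root, ]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("without transitions every marginal collapses to the tip state", {
  p <- sse_params(c(0.2, 0.2), c(0.02, 0.02), matrix(0, 2, 2))
  tr <- fix_quartet()
  st <- tip_state_map(c(A = 1, B = 1, C = 1, D = 1), 2)
  asr <- marginal_asr(tr, st, p)
  expect_true(all(abs(unclass(asr)[, 1] - 1) < 1e-12))
})

test_that("tips with observed states keep probability one on them", {
  p <- two_state_params()
  sim <- simulate_mbd_tree(p, n_extant = 12, seed = 16)
  asr <- marginal_asr(sim$tree, sim$states, p)
  tr <- attr(asr, "tree")
  for (i in seq_along(tr$tip.label)) {
    s <- sim$states[[tr$tip.label[i]]]
    expect_equal(unname(unclass(asr)[i, s]), 1)
  }
})

test_that("single-branch event counts match the CTMC rate identity", {
  ## stationary two-state chain, q symmetric 0.5, t = 1:
  ## E[# 1->2 events] = pi_1 q_12 t = 0.25
  q <- 0.5; t_len <- 1
  Q <- matrix(c(-q, q, q, -q), 2, 2, byrow = TRUE)
  uni <- reefdiv:::uniformization_setup(Q)
  P <- reefdiv:::padexp(Q, t_len)
  set.seed(77)
  n <- 10000
  count12 <- numeric(n)
  for (i in seq_len(n)) {
    a <- sample.int(2, 1)                      # pi = (1/2, 1/2)
    b <- sample.int(2, 1, prob = P[a, ])       # joint endpoint draw
    seg <- reefdiv:::sample_ctmc_path(uni, a, b, t_len, P)
    st <- seg$state
    if (length(st) > 1)
      count12[i] <- sum(st[-length(st)] == 1 & st[-1] == 2)
  }
  se <- sd(count12) / sqrt(n)
  expect_lt(abs(mean(count12) - 0.25), 3 * se)
})

test_that("degenerate mapping cases behave as documented", {
  ## Q = 0 and point-mass marginals: constant maps, zero transitions
  p <- sse_params(c(0.2, 0.2), c(0, 0), matrix(0, 2, 2))
  tr <- fix_quartet()
  st <- tip_state_map(c(A = 1, B = 1, C = 1, D = 1), 2)
  asr <- marginal_asr(tr, st, p)
  maps <- sample_histories(params = p, marginals = asr, n_maps = 4, seed = 2)
  cnt <- count_transitions(maps)
  expect_true(all(unclass(cnt)[,] == 0))
  ## impossible endpoints error with the edge identified
  uni <- reefdiv:::uniformization_setup(matrix(0, 2, 2))
  expect_error(reefdiv:::sample_ctmc_path(uni, 1, 2, 1,
                                          diag(2), edge_id = 7),
               "edge 7")
})

test_that("transition counting and chord tables follow the definitions", {
  tr <- fix_cherry()
  mk_hist <- function(seg_a, seg_b, ns) {
    character_history(tr, list(seg_a, seg_b), ns)
  }
  h1 <- mk_hist(data.frame(state = c(1, 2), duration = c(0.4, 0.6)),
                data.frame(state = c(1, 2, 1), duration = c(0.2, 0.5, 0.3)),
                c(2, 1, 1))
  expect_equal(unname(unclass(count_transitions(h1))[,]),
               matrix(c(0, 1, 2, 0), 2, 2))  # [1,2] = 2, [2,1] = 1
  ## malformed history: durations not summing to the branch length
  expect_error(mk_hist(data.frame(state = 1, duration = 0.5),
                       data.frame(state = 1, duration = 1), c(1, 1, 1)),
               "sum")
  ## averaging semantics: counts 0 and 2 -> mean 1
  h0 <- mk_hist(data.frame(state = 1, duration = 1),
                data.frame(state = 1, duration = 1), c(1, 1, 1))
  h2 <- mk_hist(data.frame(state = c(1, 2), duration = c(0.5, 0.5)),
                data.frame(state = c(1, 2), duration = c(0.7, 0.3)),
                c(2, 2, 1))
  m <- count_transitions(list(h0, h2), k = 2)
  expect_equal(unclass(m)[1, 2], 1.0)

  ## chord table round-trip
  cm <- structure(matrix(c(0, 1, 3, 0), 2, 2),
                  class = c("transition_counts", "matrix"))
  tab <- chord_table(cm, c("A", "B"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean_lineages[tab$from == "A" & tab$to == "B"], 3)
  back <- chord_to_matrix(tab)
  expect_equal(back["A", "B"], 3)
  expect_equal(back["B", "A"], 1)
  expect_error(chord_table(cm, c("A", "B", "C")), "labels")
})

test_that("sampled histories satisfy the history invariants and flow bound", {
  p <- sse_params(c(0.25, 0.25), c(0.05, 0.05), 0.15)
  sim <- simulate_mbd_tree(p, n_extant = 30, seed = 18)
  asr <- marginal_asr(sim$tree, sim$states, p)
  maps <- sample_histories(params = p, marginals = asr, n_maps = 5, seed = 9)
  tr <- attr(asr, "tree")
  for (h in maps) {
    durs <- vapply(seq_along(h$edge_segments), function(e)
      sum(h$edge_segments[[e]]$duration), 0)
    expect_equal(durs, tr$edge.length, tolerance = 1e-9)
    ## per-history flow bound: net flow out of state i is at most the
    ## number of edges whose endpoint states differ
    cnt <- attr(count_transitions(h), "total")
    boundary <- sum(h$node_states[tr$edge[, 1]] != h$node_states[tr$edge[, 2]])
    for (i in 1:2)
      expect_lte(abs(sum(cnt[i, ]) - sum(cnt[, i])), boundary)
  }
})

test_that("more maps shrink the Monte-Carlo error of mean counts", {
  p <- sse_params(c(0.25, 0.25), c(0.05, 0.05), 0.12)
  sim <- simulate_mbd_tree(p, n_extant = 25, seed = 21)
  asr <- marginal_asr(sim$tree, sim$states, p)
  mean12 <- function(n_maps, seed) {
    unclass(count_transitions(sample_histories(
      params = p, marginals = asr, n_maps = n_maps, seed = seed)))[1, 2]
  }
  v10 <- var(vapply(1:12, function(s) mean12(10, 100 + s), 0))
  v100 <- var(vapply(1:12, function(s) mean12(100, 200 + s), 0))
  expect_lt(v100, v10)
})

test_that("with state-independent rates the maps match plain Mk mapping", {
  ## two-sample check against phytools::make.simmap with the same Q
  p <- sse_params(c(0.2, 0.2), c(0.04, 0.04), 0.1)
  sim <- simulate_mbd_tree(p, n_extant = 50, seed = 25)
  asr <- marginal_asr(sim$tree, sim$states, p)
  maps <- sample_histories(params = p, marginals = asr, n_maps = 40,
                           seed = 31)
  ours <- sum(unclass(count_transitions(maps))[,])

  x <- setNames(vapply(sim$states, `[`, 1L, 1), names(sim$states))
  x <- factor(x, levels = 1:2)
  Qrow <- p$Q
  dimnames(Qrow) <- list(levels(x), levels(x))
  sm <- phytools::make.simmap(sim$tree, x, Q = Qrow, pi = "estimated",
                              nsim = 40, message = FALSE)
  theirs <- mean(vapply(sm, function(m)
    sum(vapply(m$maps, length, 0L) - 1L), 0))
  ## same order of magnitude and within 35% of each other
  expect_lt(abs(ours - theirs), 0.35 * max(ours, theirs))
})
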