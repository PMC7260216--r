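## Hand-built fixture trees -------------------------------------------------

fix_cherry <- function() ape::read.tree(text = "(A:1,B:1);")
fix_quartet <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
fix_caterpillar <- function() ape::read.tree(text = "((a:1,b:1):1,c:2);")
fix_five <- function()
  ape::read.tree(text = "(((A:0.6,B:0.6):0.9,C:1.5):0.8,(D:1.1,E:1.1):1.2);")

## ---------------------------------------------------------------------------
## Independent oracles. These share no code with the package's compiled
## pruning pass: the Euler oracle integrates the SSE system with a fixed
## fine grid in plain R; the Mk oracle uses matrix exponentials; the
## constant-rate birth-death oracle uses the closed-form branch solutions
## of the logistic extinction probability.

## fixed-step Euler integration of (E, D) along one branch
euler_branch <- function(E0, D0, len, lam, mu, Q, h = 2.5e-4) {
  k <- length(lam)
  qoff <- Q; diag(qoff) <- 0
  decay <- lam + mu + rowSums(qoff)
  nstep <- max(1L, ceiling(len / h))
  dt <- len / nstep
  E <- E0; D <- D0
  for (i in seq_len(nstep)) {
    dE <- mu - decay * E + lam * E^2 + as.numeric(qoff %*% E)
    dD <- -decay * D + 2 * lam * E * D + as.numeric(qoff %*% D)
    E <- E + dt * dE
    D <- D + dt * dD
  }
  list(E = E, D = D)
}

## full pruning pass with a caller-supplied branch propagator
prune_generic <- function(tree, tipD, lam, mu, Q, branch_fn,
                          root_mode = "fitzjohn", condition = TRUE,
                          clamp_node = NULL, clamp_state = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  k <- length(lam)
  nn <- max(tr$edge)
  nt <- length(tr$tip.label)
  D <- matrix(0, nn, k); E <- matrix(0, nn, k); lc <- numeric(nn)
  D[seq_len(nt), ] <- tipD
  done <- rep(FALSE, nn)
  clamp <- function(node) {
    if (!is.null(clamp_node) && node == clamp_node) {
      D[node, ] <<- D[node, ] * (seq_len(k) == clamp_state)
    }
  }
  for (i in seq_len(nt)) clamp(i)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (ch > nt) clamp(ch)
    if (sum(D[ch, ]) == 0) return(-Inf)
    out <- branch_fn(E[ch, ], D[ch, ], tr$edge.length[e], lam, mu, Q)
    if (!done[par]) {
      D[par, ] <- out$D; E[par, ] <- out$E; lc[par] <- lc[ch]
      done[par] <- TRUE
    } else {
      D[par, ] <- lam * D[par, ] * out$D
      E[par, ] <- (E[par, ] + out$E) / 2
      lc[par] <- lc[par] + lc[ch]
    }
    s <- sum(D[par, ])
    if (s <= 0) return(-Inf)
    D[par, ] <- D[par, ] / s; lc[par] <- lc[par] + log(s)
  }
  root <- nt + 1L
  clamp(root)
  s <- sum(D[root, ])
  if (s <= 0) return(-Inf)
  if (!is.null(clamp_node) && clamp_node == root) {
    D[root, ] <- D[root, ] / s; lc[root] <- lc[root] + log(s)
  }
  pi <- switch(root_mode,
               fitzjohn = D[root, ] / sum(D[root, ]),
               flat = rep(1 / k, k))
  lik <- sum(pi * D[root, ])
  if (condition) {
    den <- sum(pi * lam * (1 - E[root, ])^2)
    if (den <= 0) return(-Inf)
    lik <- lik / den
  }
  if (lik <= 0) return(-Inf)
  log(lik) + lc[root]
}

euler_musse_loglik <- function(tree, states, params, root_mode = "fitzjohn",
                               condition = TRUE, h = 2.5e-4) {
  tr <- ape::reorder.phylo(tree, "postorder")
  tipD <- reefdiv:::tip_state_matrix(tr, states, params$k)
  prune_generic(tr, tipD, params$lam, params$mu, params$Q,
                function(E0, D0, len, lam, mu, Q)
                  euler_branch(E0, D0, len, lam, mu, Q, h),
                root_mode, condition)
}

## Mk (pure character evolution) log-likelihood by matrix exponentials
mk_loglik <- function(tree, states, Q, pi = NULL) {
  tr <- ape::reorder.phylo(tree, "postorder")
  k <- nrow(Q)
  tipD <- reefdiv:::tip_state_matrix(tr, states, k)
  nn <- max(tr$edge); nt <- length(tr$tip.label)
  L <- matrix(1, nn, k); L[seq_len(nt), ] <- tipD
  lc <- 0
  done <- rep(FALSE, nn)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- ape::matexpo(Q * tr$edge.length[e])
    v <- as.numeric(P %*% L[ch, ])
    L[par, ] <- if (done[par]) L[par, ] * v else v
    done[par] <- TRUE
    s <- sum(L[par, ]); L[par, ] <- L[par, ] / s; lc <- lc + log(s)
  }
  pi <- pi %||% rep(1 / k, k)
  log(sum(pi * L[nt + 1L, ])) + lc
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## closed-form constant-rate birth-death branch propagation:
## u = 1 - E follows a logistic; D(t) = D0 e^{-(lam-mu) t} (u_t / u_0)^2
crbd_branch <- function(E0, D0, len, lam, mu, Q = NULL) {
  u0 <- 1 - E0
  r <- lam - mu
  if (abs(r) > 1e-12) {
    ut <- r * u0 * exp(r * len) / (r + lam * u0 * (exp(r * len) - 1))
  } else {
    ut <- u0 / (1 + lam * u0 * len)
  }
  list(E = 1 - ut, D = D0 * exp(-r * len) * (ut / u0)^2)
}

crbd_loglik <- function(tree, lam, mu, condition = TRUE) {
  nt <- length(tree$tip.label)
  tipD <- matrix(1, nt, 1)
  prune_generic(tree, tipD, lam, mu, matrix(0, 1, 1), crbd_branch,
                root_mode = "flat", condition = condition)
}

## brute-force marginal: clamp a node, recompute the full likelihood with
## an accurate branch propagator, renormalise over states
brute_marginals <- function(tree, states, params, root_mode = "fitzjohn",
                            condition = TRUE) {
  tr <- ape::reorder.phylo(tree, "postorder")
  k <- params$k
  tipD <- reefdiv:::tip_state_matrix(tr, states, k)
  branch_fn <- function(E0, D0, len, lam, mu, Q) {
    y <- reefdiv:::musse_branch_cpp(E0, D0, len, lam, mu, Q, 1e-11, 1e-13)
    list(E = y[seq_len(k)], D = y[k + seq_len(k)])
  }
  nn <- max(tr$edge)
  out <- matrix(0, nn, k)
  for (v in seq_len(nn)) {
    lls <- vapply(seq_len(k), function(s)
      prune_generic(tr, tipD, params$lam, params$mu, params$Q, branch_fn,
                    root_mode, condition, clamp_node = v, clamp_state = s), 0)
    mx <- max(lls)
    w <- exp(lls - mx); w[!is.finite(w)] <- 0
    out[v, ] <- w / sum(w)
  }
  out
}

## small simulation settings shared by several tests
two_state_params <- function() sse_params(c(0.1, 0.2), c(0.03, 0.03), 0.01)

## write a literal string to a tempfile and return its path
textConnection_file <- function(txt) {
  f <- tempfile()
  writeLines(txt, f)
  f
}
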