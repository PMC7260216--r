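#' Sample stochastic character histories from node marginals
#'
#' Draws full character histories (state segments along every branch)
#' consistent with a transition-rate matrix and precomputed node
#' marginals. Node states are drawn top-down: the root from its marginal;
#' every other node from its marginal re-weighted by the parent-to-state
#' branch transition probability, the corresponding row of
#' \eqn{e^{Q t}}. Each branch path is then drawn conditioned on its two
#' endpoint states by uniformization. Using marginals from a
#' state-dependent (MuSSE) reconstruction is what lets diversification
#' rate heterogeneity inform the mappings even though the along-branch
#' path process uses Q alone — a documented approximation shared with
#' standard mapping tools.
#'
#' The `"joint"` method instead draws node states from the standard
#' top-down joint conditional (pruning partials of the pure character
#' process), provided for comparison.
#'
#' @param tree Rooted binary `phylo`; ignored (with a warning) if
#'   `marginals` carries its own tree.
#' @param params An [sse_params]; only `Q` is used for the along-branch
#'   process.
#' @param marginals A `node_marginals` from [marginal_asr] (required for
#'   the default method).
#' @param n_maps Number of independent histories (default 10).
#' @param seed Integer seed.
#' @param method `"marginal"` (default) or `"joint"`.
#' @param states Tip states; required for `method = "joint"`.
#' @param max_retries Resampling budget when a drawn endpoint pair has
#'   zero transition probability (e.g. q = 0 between the endpoints).
#' @return List of `character_history` objects (length `n_maps`).
#' @export
sample_histories <- function(tree = NULL, params, marginals = NULL,
                             n_maps = 10, seed = 1L,
                             method = c("marginal", "joint"),
                             states = NULL, max_retries = 100) {
  method <- match.arg(method)
  params <- validate_sse_params(params)
  k <- params$k
  if (method == "marginal") {
    if (is.null(marginals)) stop_reefdiv("marginal method needs marginals")
    tr <- attr(marginals, "tree") %||% tree
    probs <- unclass(marginals)[,]
  } else {
    if (is.null(states)) stop_reefdiv("joint method needs tip states")
    tr <- ape::reorder.phylo(tree, "postorder")
    probs <- mk_partials(tr, tip_state_matrix(tr, states, k), params$Q)
  }
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  edge <- tr$edge
  elen <- tr$edge.length
  ## preorder: parents before children
  preord <- rev(ape::postorder(tr))
  Pt <- lapply(seq_len(nrow(edge)), function(e) padexp(params$Q, elen[e]))
  uni <- uniformization_setup(params$Q)

  set.seed(seed)
  lapply(seq_len(n_maps), function(m) {
    node_states <- draw_node_states(tr, probs, Pt, preord, root, method,
                                    max_retries)
    segs <- vector("list", nrow(edge))
    for (e in seq_len(nrow(edge))) {
      a <- node_states[edge[e, 1]]; b <- node_states[edge[e, 2]]
      path <- sample_ctmc_path(uni, a, b, elen[e], Pt[[e]], max_retries, e)
      segs[[e]] <- path
    }
    character_history(tr, segs, node_states)
  })
}

draw_node_states <- function(tr, probs, Pt, preord, root, method,
                             max_retries) {
  nnode <- max(tr$edge)
  node_states <- integer(nnode)
  for (attempt in seq_len(max_retries)) {
    node_states[root] <- sample_state(probs[root, ])
    ok <- TRUE
    for (e in preord) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      w <- probs[ch, ] * Pt[[e]][node_states[par], ]
      if (sum(w) <= 0) { ok <- FALSE; break }
      node_states[ch] <- sample_state(w)
    }
    if (ok) return(node_states)
  }
  stop_reefdiv(
    "could not draw node states consistent with the branch process (edge %d)", e)
}

sample_state <- function(w) {
  if (length(w) == 1L) return(1L)
  sample.int(length(w), 1L, prob = w)
}

## Mk pruning partials (subtree likelihoods) per node, for the joint method
mk_partials <- function(tr, tipD, Q) {
  k <- ncol(tipD)
  nnode <- max(tr$edge)
  ntip <- nrow(tipD)
  L <- matrix(1, nnode, k)
  L[seq_len(ntip), ] <- tipD
  for (e in seq_len(nrow(tr$edge))) {  # postorder
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    P <- padexp(Q, tr$edge.length[e])
    w <- L[par, ] * as.numeric(P %*% L[ch, ])
    L[par, ] <- w / max(sum(w), 1e-300)
  }
  L
}

## matrix exponential of Q*t (ape's C implementation)
padexp <- function(Q, t) {
  P <- ape::matexpo(Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

uniformization_setup <- function(Q) {
  k <- nrow(Q)
  omega <- max(-diag(Q)) * 1.05 + 1e-12
  R <- diag(k) + Q / omega
  list(Q = Q, k = k, omega = omega, R = R)
}

## Endpoint-conditioned CTMC path on one branch by uniformization:
## draw the dominating-Poisson jump count from its conditional
## distribution, place the jumps uniformly, fill in states with the
## bridge kernel, then drop virtual (self) jumps.
sample_ctmc_path <- function(uni, a, b, len, P = NULL, max_retries = 100,
                             edge_id = NA) {
  k <- uni$k; omega <- uni$omega; R <- uni$R
  if (len <= 0) {
    if (a != b)
      stop_reefdiv("zero-length edge %s with differing endpoint states", edge_id)
    return(data.frame(state = a, duration = 0))
  }
  P <- P %||% padexp(uni$Q, len)
  pab <- P[a, b]
  if (pab <= 0)
    stop_reefdiv(
      "endpoint pair (%d -> %d) has zero transition probability on edge %s",
      a, b, edge_id)
  ## jump-count distribution: P(N = n) = dpois(n, omega*len) R^n[a,b] / pab
  mu <- omega * len
  u <- runif(1)
  n <- -1L
  cum <- 0
  Rpow <- diag(k)
  Rlist <- list(Rpow)
  repeat {
    n <- n + 1L
    if (n > 0) {
      Rpow <- Rpow %*% R
      Rlist[[n + 1L]] <- Rpow
    }
    cum <- cum + exp(dpois_log(n, mu)) * Rpow[a, b] / pab
    if (u <= cum || n > 10000L) break
  }
  if (n == 0L) return(data.frame(state = a, duration = len))
  times <- sort(runif(n, 0, len))
  st <- integer(n + 1L)
  st[1] <- a
  cur <- a
  for (j in seq_len(n)) {
    ## state after jump j, conditioned on reaching b after the rest
    w <- R[cur, ] * vapply(seq_len(k), function(s) Rlist[[n - j + 1L]][s, b], 0)
    cur <- sample_state(w)
    st[j + 1L] <- cur
  }
  ## collapse virtual jumps: interval i starts at c(0, times)[i] in state st[i]
  starts <- c(0, times)
  keep <- c(TRUE, diff(st) != 0)
  seg_start <- starts[keep]
  seg_end <- c(seg_start[-1], len)
  data.frame(state = st[keep], duration = seg_end - seg_start)
}

dpois_log <- function(n, mu) n * log(mu) - mu - lgamma(n + 1)

#' Count state transitions across character histories
#'
#' Counts every i -> j segment boundary in each history and averages the
#' counts across histories, giving the mean number of lineages making
#' each transition per map (and per tree, when histories from several
#' trees are pooled).
#'
#' @param histories A `character_history` or list of them (may span
#'   several trees of identical state count).
#' @param k Number of states; inferred from the histories if missing.
#' @return A `transition_counts` object: k x k matrix of mean counts
#'   (diagonal zero) with attributes `n_maps` and `total` (the summed
#'   integer counts).
#' @export
count_transitions <- function(histories, k = NULL) {
  if (inherits(histories, "character_history")) histories <- list(histories)
  if (!length(histories)) stop_reefdiv("no histories given")
  maxstate <- max(vapply(histories, function(h)
    max(vapply(h$edge_segments, function(s) max(s$state), 0)), 0))
  k <- k %||% maxstate
  if (maxstate > k) stop_reefdiv("history states exceed k = %d", k)
  tot <- matrix(0, k, k)
  for (h in histories) {
    segs <- h$edge_segments
    if (!is.null(h$root_edge_segments))
      segs <- c(segs, list(h$root_edge_segments))
    for (s in segs) {
      ns <- nrow(s)
      if (ns > 1) {
        from <- s$state[-ns]; to <- s$state[-1]
        for (ii in seq_along(from))
          tot[from[ii], to[ii]] <- tot[from[ii], to[ii]] + 1
      }
    }
  }
  m <- tot / length(histories)
  diag(m) <- 0
  structure(m, class = c("transition_counts", class(m)),
            n_maps = length(histories), total = tot)
}

#' Long-format transition table for chord diagrams
#'
#' @param counts A `transition_counts` matrix.
#' @param labels State labels (length k).
#' @return Data frame with `from`, `to`, `mean_lineages`; k(k-1) rows,
#'   diagonal omitted.
#' @export
chord_table <- function(counts, labels = NULL) {
  k <- nrow(counts)
  labels <- labels %||% as.character(seq_len(k))
  if (length(labels) != k)
    stop_reefdiv("need %d state labels, got %d", k, length(labels))
  idx <- which(row(counts) != col(counts))
  data.frame(from = labels[row(counts)[idx]],
             to = labels[col(counts)[idx]],
             mean_lineages = as.numeric(unclass(counts)[,])[idx],
             stringsAsFactors = FALSE)
}

#' Rebuild a transition matrix from a chord table
#' @param tab Data frame from [chord_table].
#' @return k x k matrix with zero diagonal.
#' @export
chord_to_matrix <- function(tab) {
  labels <- unique(c(tab$from, tab$to))
  k <- length(labels)
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(nrow(tab))) m[tab$from[i], tab$to[i]] <- tab$mean_lineages[i]
  m
}
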