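#' Multi-state birth-death parameter bundle
#'
#' Bundles per-state speciation rates \eqn{\lambda_i}, extinction rates
#' \eqn{\mu_i} (events per Myr) and a character transition-rate matrix
#' \eqn{q_{ij}} (per Myr) for a k-state speciation-extinction (MuSSE)
#' process. The diagonal of `Q` is always set to minus the row's
#' off-diagonal sum, so rows sum to zero.
#'
#' @param lam Numeric vector of per-state speciation rates, length k.
#' @param mu Numeric vector of per-state extinction rates, length k.
#' @param Q k x k matrix of transition rates; off-diagonal entries must be
#'   non-negative, the diagonal is recomputed. A scalar is interpreted as a
#'   symmetric all-rates-equal matrix.
#' @param states Optional character vector of state labels (length k).
#' @return An object of class `sse_params` with elements `k`, `lam`, `mu`,
#'   `Q` and `states`. Net diversification `lam - mu` is derived on demand,
#'   never stored.
#' @examples
#' p <- sse_params(lam = c(0.1, 0.2), mu = c(0.03, 0.03), Q = 0.01)
#' net_div(p)
#' @export
sse_params <- function(lam, mu, Q, states = NULL) {
  k <- length(lam)
  if (k < 1) stop_reefdiv("need at least one state")
  if (length(mu) != k) stop_reefdiv("lam and mu lengths differ (%d vs %d)", k, length(mu))
  if (any(!is.finite(lam)) || any(lam < 0)) stop_reefdiv("speciation rates must be finite and >= 0")
  if (any(!is.finite(mu)) || any(mu < 0)) stop_reefdiv("extinction rates must be finite and >= 0")
  if (is.matrix(Q)) {
    if (!all(dim(Q) == k)) stop_reefdiv("Q must be %d x %d", k, k)
  } else if (length(Q) == 1) {
    Q <- matrix(Q, k, k)
  } else {
    stop_reefdiv("Q must be a k x k matrix or a scalar rate")
  }
  diag(Q) <- 0
  if (any(Q < 0)) stop_reefdiv("off-diagonal transition rates must be >= 0")
  diag(Q) <- -rowSums(Q)
  states <- states %||% as.character(seq_len(k))
  if (length(states) != k) stop_reefdiv("states must have length k")
  structure(list(k = k, lam = as.numeric(lam), mu = as.numeric(mu),
                 Q = unname(Q), states = states),
            class = "sse_params")
}

#' @export
print.sse_params <- function(x, ...) {
  cat(sprintf("MuSSE parameters, k = %d states (%s)\n", x$k,
              paste(x$states, collapse = ", ")))
  m <- rbind(lambda = x$lam, mu = x$mu, r = x$lam - x$mu)
  colnames(m) <- x$states
  print(round(m, 4))
  cat("Q (per Myr):\n")
  print(round(x$Q, 4))
  invisible(x)
}

#' Net diversification rates
#'
#' @param params An [sse_params] object.
#' @return Numeric vector `lam - mu`, one entry per state.
#' @export
net_div <- function(params) params$lam - params$mu

validate_sse_params <- function(params) {
  if (!inherits(params, "sse_params")) {
    if (is.list(params) && all(c("lam", "mu", "Q") %in% names(params))) {
      params <- sse_params(params$lam, params$mu, params$Q, params$states)
    } else {
      stop_reefdiv("not an sse_params object")
    }
  }
  stopifnot(max(abs(rowSums(params$Q))) < 1e-12)
  params
}

#' Normalise tip-state input to a tip-state map
#'
#' A tip-state map assigns each tip label its set of admissible states:
#' a singleton for an observed state, several states for ambiguous or
#' missing data. Accepts a named integer vector (observed states) or a
#' named list of integer vectors.
#'
#' @param states Named integer vector or named list of integer vectors.
#' @param k Number of states.
#' @return Named list of sorted integer vectors, class `tip_state_map`.
#' @export
tip_state_map <- function(states, k) {
  if (is.list(states)) {
    out <- lapply(states, function(s) sort(unique(as.integer(s))))
  } else {
    out <- lapply(as.integer(states), function(s) s)
    names(out) <- names(states)
  }
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop_reefdiv("tip states must be named by tip label")
  bad <- vapply(out, function(s) length(s) == 0 || any(s < 1 | s > k), TRUE)
  if (any(bad))
    stop_reefdiv("invalid state set for tip(s): %s",
                 paste(names(out)[bad], collapse = ", "))
  structure(out, class = "tip_state_map", k = k)
}

## tip-state map -> ntip x k 0/1 indicator matrix in the tree's tip order
tip_state_matrix <- function(tree, states, k) {
  if (!inherits(states, "tip_state_map")) states <- tip_state_map(states, k)
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing))
    stop_reefdiv("no state entry for tip(s): %s",
                 paste(head(missing, 5), collapse = ", "))
  m <- matrix(0, length(tree$tip.label), k)
  for (i in seq_along(tree$tip.label)) {
    m[i, states[[tree$tip.label[i]]]] <- 1
  }
  m
}
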