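## ---- full parameter vector layout -----------------------------------------
## c(lam_1..k, mu_1..k, q_offdiag row by row), names lam1.., mu1.., q12..
par_names <- function(k) {
  qn <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    qn <- c(qn, sprintf("q%d%d", i, j))
  c(paste0("lam", seq_len(k)), paste0("mu", seq_len(k)), qn)
}

params_to_vec <- function(params) {
  k <- params$k
  q <- numeric(0)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    q <- c(q, params$Q[i, j])
  setNames(c(params$lam, params$mu, q), par_names(k))
}

vec_to_params <- function(v, k, states = NULL) {
  lam <- v[seq_len(k)]
  mu <- v[k + seq_len(k)]
  Q <- matrix(0, k, k)
  idx <- 2 * k
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    idx <- idx + 1
    Q[i, j] <- v[idx]
  }
  sse_params(lam, mu, Q, states)
}

## A tying map assigns every entry of the full vector either a free-parameter
## index (>= 1) or 0 = held at `fixed`. It must use each free index at least
## once and cover the vector exactly (a partition of the full layout).
check_par_map <- function(par_map, n_full) {
  if (length(par_map) != n_full)
    stop_reefdiv("par_map must cover all %d parameters", n_full)
  free <- par_map[par_map > 0]
  nf <- max(c(0L, free))
  if (nf == 0) stop_reefdiv("par_map leaves no free parameters")
  if (!setequal(unique(free), seq_len(nf)))
    stop_reefdiv("par_map free indices must be 1..n without gaps")
  nf
}

expand_par <- function(free, par_map, fixed) {
  out <- fixed
  sel <- par_map > 0
  out[sel] <- free[par_map[sel]]
  out
}

## Crude but serviceable starting point: a tree-wide Yule-like rate split
## equally across states, a tenth of it as extinction, a fifth as transition.
musse_start_heuristic <- function(tree, k) {
  n <- length(tree$tip.label)
  h <- max(ape::node.depth.edgelength(tree))
  r <- max(log(n / 2) / max(h, 1e-8), 1e-4)
  sse_params(rep(r, k), rep(r / 10, k), matrix(r / 5, k, k))
}

## Closure evaluating the log-likelihood for a free-parameter vector,
## with tree preprocessing done once.
musse_lik_factory <- function(tree, states, k, options,
                              par_map = NULL, fixed = NULL) {
  pp <- musse_prep(tree, states, k, options)
  n_full <- 2 * k + k * (k - 1)
  par_map <- par_map %||% seq_len(n_full)
  fixed <- fixed %||% numeric(n_full)
  check_par_map(par_map, n_full)
  ntip <- length(pp$tr$tip.label)
  function(free) {
    v <- expand_par(free, par_map, fixed)
    if (any(!is.finite(v)) || any(v < 0)) return(-Inf)
    p <- vec_to_params(v, k)
    musse_loglik_cpp(pp$tr$edge, pp$tr$edge.length, ntip, pp$tipD,
                     p$lam, p$mu, p$Q, pp$rm_code, pp$pi_given,
                     options$condition_survival, options$rtol, options$atol)
  }
}

#' Maximum-likelihood MuSSE fit
#'
#' Maximises the MuSSE log-likelihood over per-state speciation and
#' extinction rates and transition rates, on the log scale with box
#' constraints, using L-BFGS-B with restarts. Parameters can be tied to
#' one another or held fixed through `par_map`/`fixed`, which is how
#' hidden-regime (HiSSE-style) models built by [expand_hidden] are
#' fitted with the same machinery.
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param states Tip states (see [tip_state_map]).
#' @param k Number of (possibly expanded) states; defaults to the number
#'   implied by `init` or `states`.
#' @param init An [sse_params] starting point, or `NULL` for a heuristic
#'   start (a tree-wide Yule-type rate split across states).
#' @param par_map Optional integer tying map over the full parameter
#'   vector `c(lam, mu, q_offdiag)`: entry j > 0 assigns position j to
#'   free parameter j; 0 holds it at `fixed[j]`.
#' @param fixed Values for positions with `par_map == 0` (default 0).
#' @param bounds Length-2 positive bounds on every free rate.
#' @param options An [sse_options].
#' @param restarts Restart budget; the fit is flagged unconverged (not an
#'   error) if a restart still improves the log-likelihood by > 1e-4.
#' @return An `sse_fit`: `params` (point estimate as [sse_params]),
#'   `loglik`, `converged`, `free` (named free-parameter vector),
#'   `par_map`, `fixed`, `options`, `counts`.
#' @examples
#' p <- sse_params(c(0.15, 0.3), c(0.02, 0.02), 0.03)
#' sim <- simulate_mbd_tree(p, n_extant = 60, seed = 11)
#' fit <- musse_ml(sim$tree, sim$states, k = 2)
#' fit$params$lam
#' @export
musse_ml <- function(tree, states, k = NULL, init = NULL, par_map = NULL,
                     fixed = NULL, bounds = c(1e-7, 1e3),
                     options = sse_options(), restarts = 3) {
  if (is.null(k)) {
    k <- if (!is.null(init)) init$k else max(unlist(states))
  }
  if (any(bounds <= 0) || bounds[1] >= bounds[2])
    stop_reefdiv("bounds must be positive and increasing")
  n_full <- 2 * k + k * (k - 1)
  par_map <- par_map %||% seq_len(n_full)
  fixed <- fixed %||% numeric(n_full)
  nf <- check_par_map(par_map, n_full)
  init <- init %||% musse_start_heuristic(tree, k)
  init_full <- params_to_vec(validate_sse_params(init))
  free0 <- vapply(seq_len(nf), function(i) {
    mean(init_full[par_map == i])
  }, 0)
  free0 <- pmin(pmax(free0, bounds[1] * 1.01), bounds[2] * 0.99)
  lik <- musse_lik_factory(tree, states, k, options, par_map, fixed)

  negll <- function(lpar) {
    v <- -lik(exp(lpar))
    if (!is.finite(v)) 1e10 else v
  }
  lp <- log(free0)
  lo <- rep(log(bounds[1]), nf); hi <- rep(log(bounds[2]), nf)
  best <- NULL
  nevals <- 0L
  converged <- FALSE
  for (r in seq_len(restarts + 1)) {
    op <- try(optim(lp, negll, method = "L-BFGS-B", lower = lo, upper = hi,
                    control = list(maxit = 500, factr = 1e7)), silent = TRUE)
    if (inherits(op, "try-error")) {
      op <- optim(lp, negll, method = "Nelder-Mead",
                  control = list(maxit = 2000))
      op$par <- pmin(pmax(op$par, lo), hi)
    }
    nevals <- nevals + (op$counts[1] %||% 0)
    if (!is.null(best) && best$value - op$value <= 1e-4) {
      converged <- TRUE
      if (op$value < best$value) best <- op
      break
    }
    if (is.null(best) || op$value < best$value) best <- op
    lp <- best$par
  }
  free_hat <- setNames(exp(best$par), paste0("p", seq_len(nf)))
  full <- expand_par(free_hat, par_map, fixed)
  params <- vec_to_params(full, k)
  structure(list(params = params, loglik = -best$value,
                 converged = converged, free = free_hat,
                 par_map = par_map, fixed = fixed, k = k,
                 options = options, counts = nevals),
            class = "sse_fit")
}

#' @export
print.sse_fit <- function(x, ...) {
  cat(sprintf("MuSSE %s fit: logLik = %.4f (%d free parameter(s))%s\n",
              if (x$converged) "ML" else "ML [NOT CONVERGED]",
              x$loglik, length(x$free),
              if (x$converged) "" else " - treat with caution"))
  print(x$params)
  invisible(x)
}

#' AIC for SSE fits
#' @param object An `sse_fit`.
#' @param ... Unused.
#' @param k Penalty per parameter (2 = AIC).
#' @export
AIC.sse_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * length(object$free)
}

#' Hidden-regime (HiSSE-style) model specification
#'
#' Describes a state-space expansion in which each of `n_observed`
#' character states is split into `n_hidden` unobserved diversification
#' regimes. Expanded state `(s, h)` gets index `s + (h-1) * n_observed`.
#' Two stock tying schemes cover the usual comparison:
#' `"unconstrained"` gives every expanded state its own speciation and
#' extinction rate (rates differ between observed states, with a hidden
#' regime per state), while `"cid"` (character-independent) ties rates
#' across observed states within a hidden layer, so only the hidden
#' regime carries rate variation. In both, observed-state transitions
#' `q_ij` are shared across hidden layers, hidden-regime switches happen
#' at one common rate, and simultaneous observed+hidden changes are
#' disallowed (rate 0).
#'
#' @param n_observed Number of observed states.
#' @param n_hidden Hidden regimes per observed state (default 2).
#' @param model `"unconstrained"` or `"cid"`.
#' @return A `hidden_spec` list with the expanded `k` and tying maps.
#' @export
hidden_spec <- function(n_observed, n_hidden = 2,
                        model = c("unconstrained", "cid")) {
  model <- match.arg(model)
  stopifnot(n_observed >= 1, n_hidden >= 1)
  ko <- n_observed; kh <- n_hidden; k <- ko * kh
  obs_of <- rep(seq_len(ko), kh)     # expanded index -> observed state
  hid_of <- rep(seq_len(kh), each = ko)
  n_full <- 2 * k + k * (k - 1)
  par_map <- integer(n_full)
  fixed <- numeric(n_full)
  next_free <- 0L
  new_free <- function() { next_free <<- next_free + 1L; next_free }
  ## lambda, mu
  if (model == "unconstrained") {
    lam_idx <- matrix(0L, ko, kh); mu_idx <- matrix(0L, ko, kh)
    for (h in seq_len(kh)) for (s in seq_len(ko)) lam_idx[s, h] <- new_free()
    for (h in seq_len(kh)) for (s in seq_len(ko)) mu_idx[s, h] <- new_free()
    for (e in seq_len(k)) par_map[e] <- lam_idx[obs_of[e], hid_of[e]]
    for (e in seq_len(k)) par_map[k + e] <- mu_idx[obs_of[e], hid_of[e]]
  } else {
    lam_h <- vapply(seq_len(kh), function(h) new_free(), 0L)
    mu_h <- vapply(seq_len(kh), function(h) new_free(), 0L)
    for (e in seq_len(k)) par_map[e] <- lam_h[hid_of[e]]
    for (e in seq_len(k)) par_map[k + e] <- mu_h[hid_of[e]]
  }
  ## transitions: q_obs shared across layers, one hidden-switch rate
  qobs_idx <- matrix(0L, ko, ko)
  for (i in seq_len(ko)) for (j in seq_len(ko)) if (i != j)
    qobs_idx[i, j] <- new_free()
  alpha_idx <- if (kh > 1) new_free() else 0L
  pos <- 2 * k
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    pos <- pos + 1
    same_h <- hid_of[i] == hid_of[j]
    same_o <- obs_of[i] == obs_of[j]
    if (same_h && !same_o) {
      par_map[pos] <- qobs_idx[obs_of[i], obs_of[j]]
    } else if (same_o && !same_h) {
      par_map[pos] <- alpha_idx
    }  # else dual transition: fixed at 0
  }
  structure(list(n_observed = ko, n_hidden = kh, k = k, model = model,
                 par_map = par_map, fixed = fixed,
                 obs_of = obs_of, hid_of = hid_of),
            class = "hidden_spec")
}

#' Expand tip states and parameters for a hidden-regime model
#'
#' Tips observed in state s become ambiguous over all expanded states
#' `(s, h)`; the likelihood machinery is unchanged and simply runs on the
#' expanded state space with the specification's tying map. With `n_hidden = 1`
#' the expansion is the identity.
#'
#' @param spec A [hidden_spec].
#' @param base_states Tip states on the observed state space.
#' @param init Optional [sse_params] on the observed space used to seed
#'   the expanded template (defaults to mild generic rates).
#' @return List: `states` (expanded [tip_state_map]), `params_template`
#'   (expanded [sse_params] start values), `par_map`, `fixed`, `spec`.
#' @export
expand_hidden <- function(spec, base_states, init = NULL) {
  stopifnot(inherits(spec, "hidden_spec"))
  ko <- spec$n_observed; kh <- spec$n_hidden; k <- spec$k
  base_states <- tip_state_map(base_states, ko)
  exp_states <- lapply(base_states, function(s) {
    as.integer(outer(s, (seq_len(kh) - 1) * ko, `+`))
  })
  names(exp_states) <- names(base_states)
  if (is.null(init)) {
    lam <- rep(0.1, k); mu <- rep(0.02, k)
    Q <- matrix(0.01, k, k)
  } else {
    lam <- init$lam[spec$obs_of]
    mu <- init$mu[spec$obs_of]
    Q <- matrix(0.01, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      Q[i, j] <- if (spec$hid_of[i] == spec$hid_of[j] &&
                     spec$obs_of[i] != spec$obs_of[j])
        init$Q[spec$obs_of[i], spec$obs_of[j]] else 0.01
    }
  }
  ## zero out dual transitions in the template so it satisfies the tying
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    if (spec$hid_of[i] != spec$hid_of[j] && spec$obs_of[i] != spec$obs_of[j])
      Q[i, j] <- 0
  }
  list(states = tip_state_map(exp_states, k),
       params_template = sse_params(lam, mu, Q),
       par_map = spec$par_map, fixed = spec$fixed, spec = spec)
}

#' Collapse expanded-state draws or estimates to observed states
#'
#' Sums nothing and chooses nothing clever: speciation/extinction rates
#' of an observed state under a hidden-regime model are reported per
#' expanded state; this helper just labels them `s<obs>.h<hidden>`.
#'
#' @param spec A [hidden_spec].
#' @return Character labels for the expanded states.
#' @export
expanded_state_labels <- function(spec) {
  sprintf("s%d.h%d", spec$obs_of, spec$hid_of)
}
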