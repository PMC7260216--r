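#' Bayesian sampling of MuSSE parameters
#'
#' Samples the posterior of the (free) MuSSE parameters under independent
#' exponential priors, using univariate slice sampling with stepping-out
#' (the default; essentially tuning-free) or random-walk Metropolis. A
#' short preliminary run tunes the slice widths (or proposal scales) per
#' parameter; the main chain then runs `n_gen` generations, one update of
#' every parameter per generation. The first `burn_frac` of the main
#' chain is discarded and per-parameter effective sample sizes are
#' computed from the retained draws; a warning is raised when any ESS
#' falls below `ess_warn`.
#'
#' The default prior rate follows the usual working heuristic of
#' exponential priors with rate \eqn{1/(2\hat r)}, where \eqn{\hat r} is
#' the tree-wide Yule-type net diversification estimate, so the prior
#' mean is twice the characteristic rate of the tree.
#'
#' @param tree,states,k As in [musse_ml].
#' @param start An `sse_fit` (its point estimate seeds the chain) or an
#'   [sse_params]. Using an unconverged fit is allowed but warned about.
#' @param prior_rate Exponential prior rate, scalar or one per free
#'   parameter; `NULL` for the heuristic above.
#' @param n_gen Main-chain generations (default 2000).
#' @param n_prelim Preliminary tuning generations (default 100).
#' @param burn_frac Fraction of the main chain discarded (default 0.10).
#' @param sampler `"slice"` or `"rw"`.
#' @param par_map,fixed Optional tying map (see [musse_ml]).
#' @param options An [sse_options].
#' @param seed Integer seed; fixed seed and inputs give an identical
#'   draw matrix.
#' @param prior_only Sample the prior alone (likelihood switched off);
#'   used for sampler validation.
#' @param ess_warn ESS warning threshold (default 200).
#' @return A `posterior_draws` object: `draws` (matrix of post-burn-in
#'   full parameter vectors, one row per retained generation), `free`
#'   (free-parameter draws), `logpost`, `ess`, `k`, `par_map`, `fixed`,
#'   `burn_frac`, `seed`, `tree_id`.
#' @export
musse_mcmc <- function(tree, states, k = NULL, start, prior_rate = NULL,
                       n_gen = 2000, n_prelim = 100, burn_frac = 0.10,
                       sampler = c("slice", "rw"), par_map = NULL,
                       fixed = NULL, options = sse_options(), seed = 1L,
                       prior_only = FALSE, ess_warn = 200, tree_id = 1L) {
  sampler <- match.arg(sampler)
  if (inherits(start, "sse_fit")) {
    if (!start$converged)
      warning("starting MCMC from an unconverged fit")
    k <- k %||% start$k
    par_map <- par_map %||% start$par_map
    fixed <- fixed %||% start$fixed
    start_params <- start$params
  } else {
    start_params <- validate_sse_params(start)
    k <- k %||% start_params$k
  }
  n_full <- 2 * k + k * (k - 1)
  par_map <- par_map %||% seq_len(n_full)
  fixed <- fixed %||% numeric(n_full)
  nf <- check_par_map(par_map, n_full)
  full0 <- params_to_vec(start_params)
  x <- vapply(seq_len(nf), function(i) mean(full0[par_map == i]), 0)
  x <- pmax(x, 1e-6)

  if (is.null(prior_rate)) {
    n <- length(tree$tip.label)
    h <- max(ape::node.depth.edgelength(tree))
    rhat <- max(log(n / 2) / max(h, 1e-8), 1e-4)
    prior_rate <- 1 / (2 * rhat)
  }
  prior_rate <- rep_len(prior_rate, nf)
  if (any(prior_rate <= 0)) stop_reefdiv("prior rates must be > 0")

  lik <- if (prior_only) function(free) 0 else
    musse_lik_factory(tree, states, k, options, par_map, fixed)
  logpost <- function(free) {
    if (any(free < 0)) return(-Inf)
    lp <- sum(dexp(free, prior_rate, log = TRUE))
    if (!is.finite(lp)) return(-Inf)
    ll <- lik(free)
    if (!is.finite(ll)) return(-Inf)
    ll + lp
  }

  set.seed(seed)
  f0 <- logpost(x)
  if (!is.finite(f0)) stop_reefdiv("log-posterior not finite at the start point")

  w <- pmax(abs(x), 0.05)  # initial slice widths / proposal sds
  run_chain <- function(x, f0, n, w, record) {
    draws <- if (record) matrix(NA_real_, n, nf) else NULL
    lps <- if (record) numeric(n) else NULL
    accept <- 0L
    for (g in seq_len(n)) {
      for (i in seq_len(nf)) {
        if (sampler == "slice") {
          up <- slice_update1(x, i, logpost, f0, w[i])
        } else {
          up <- rw_update1(x, i, logpost, f0, w[i])
          accept <- accept + up$accepted
        }
        x <- up$x; f0 <- up$f
      }
      if (record) { draws[g, ] <- x; lps[g] <- f0 }
    }
    list(x = x, f = f0, draws = draws, logpost = lps, accept = accept)
  }

  ## preliminary run: tune widths from the spread of the draws
  if (n_prelim > 0) {
    pre <- run_chain(x, f0, n_prelim, w, record = TRUE)
    spread <- apply(pre$draws, 2, function(z) diff(quantile(z, c(0.05, 0.95))))
    w <- ifelse(spread > 0, spread, w)
    if (sampler == "rw") w <- pmax(w / 2, 1e-6)
    x <- pre$x; f0 <- pre$f
  }
  main <- run_chain(x, f0, n_gen, w, record = TRUE)
  if (sampler == "rw" && main$accept == 0)
    stop_reefdiv(paste("random-walk chain accepted no proposals;",
                       "reduce the proposal scale or use the slice sampler"))
  keep <- seq.int(floor(burn_frac * n_gen) + 1, n_gen)
  freed <- main$draws[keep, , drop = FALSE]
  colnames(freed) <- paste0("p", seq_len(nf))
  full <- t(apply(freed, 1, expand_par, par_map = par_map, fixed = fixed))
  colnames(full) <- par_names(k)
  essv <- apply(freed, 2, ess)
  if (any(!is.na(essv) & essv < ess_warn))
    warning(sprintf("low effective sample size (min %.0f < %d)",
                    min(essv, na.rm = TRUE), ess_warn))
  structure(list(draws = full, free = freed, logpost = main$logpost[keep],
                 ess = essv, k = k, par_map = par_map, fixed = fixed,
                 burn_frac = burn_frac, n_gen = n_gen, seed = seed,
                 sampler = sampler, prior_rate = prior_rate,
                 tree_id = tree_id),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "MuSSE posterior: %d retained draws (%s sampler, burn-in %.0f%%), k = %d\n",
    nrow(x$draws), x$sampler, 100 * x$burn_frac, x$k))
  cat(sprintf("  min ESS: %.0f\n", suppressWarnings(min(x$ess, na.rm = TRUE))))
  invisible(x)
}

## one univariate slice-sampling update with stepping out (Neal 2003),
## truncated at 0
slice_update1 <- function(x, i, logf, f0, w, max_steps = 30) {
  y <- f0 - rexp(1)
  u <- runif(1)
  L <- x[i] - w * u
  R <- L + w
  fL <- function(v) { x[i] <- v; logf(x) }
  j <- floor(runif(1) * max_steps)
  kk <- max_steps - 1 - j
  while (j > 0 && L > 0 && fL(L) > y) { L <- L - w; j <- j - 1 }
  if (L < 0) L <- 0
  while (kk > 0 && fL(R) > y) { R <- R + w; kk <- kk - 1 }
  repeat {
    x1 <- runif(1, L, R)
    f1 <- fL(x1)
    if (f1 >= y) { x[i] <- x1; return(list(x = x, f = f1)) }
    if (x1 < x[i]) L <- x1 else R <- x1
    if (R - L < 1e-12) { return(list(x = x, f = f0)) }
  }
}

## one random-walk Metropolis update (normal proposal, reflected at 0)
rw_update1 <- function(x, i, logf, f0, sdi) {
  x1 <- x
  x1[i] <- abs(x[i] + rnorm(1, 0, sdi))
  f1 <- logf(x1)
  if (is.finite(f1) && log(runif(1)) < f1 - f0)
    list(x = x1, f = f1, accepted = 1L)
  else
    list(x = x, f = f0, accepted = 0L)
}

#' Pool posterior draw sets and summarise rates
#'
#' Concatenates post-burn-in draws from several trees (the draw sets must
#' share one parameter schema), derives per-draw net diversification
#' rates \eqn{r_i = \lambda_i - \mu_i}, and reports for every parameter
#' and every \eqn{r_i} the kernel-density mode and a central credibility
#' interval.
#'
#' @param draw_sets A `posterior_draws` object or list of them.
#' @param level Credibility level (default 0.95).
#' @return A data frame with columns `param`, `mode`, `lo`, `hi`,
#'   `n_draws`, plus the pooled draw matrix as attribute `"pooled"`.
#' @export
pool_and_summarize <- function(draw_sets, level = 0.95) {
  if (inherits(draw_sets, "posterior_draws")) draw_sets <- list(draw_sets)
  if (!length(draw_sets)) stop_reefdiv("empty draw pool")
  schema <- colnames(draw_sets[[1]]$draws)
  for (d in draw_sets)
    if (!identical(colnames(d$draws), schema))
      stop_reefdiv("draw sets have different parameter schemas")
  pooled <- do.call(rbind, lapply(draw_sets, `[[`, "draws"))
  k <- draw_sets[[1]]$k
  r <- pooled[, seq_len(k), drop = FALSE] -
    pooled[, k + seq_len(k), drop = FALSE]
  colnames(r) <- paste0("r", seq_len(k))
  all <- cbind(pooled, r)
  a <- (1 - level) / 2
  out <- data.frame(
    param = colnames(all),
    mode = apply(all, 2, density_mode),
    lo = apply(all, 2, quantile, probs = a),
    hi = apply(all, 2, quantile, probs = 1 - a),
    n_draws = nrow(all), row.names = NULL)
  attr(out, "pooled") <- all
  attr(out, "level") <- level
  out
}
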