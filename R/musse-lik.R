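#' Likelihood options for SSE computations
#'
#' @param root_mode How the state distribution at the root is treated:
#'   `"fitzjohn"` (default) weights each state by its share of the root
#'   partial likelihood, `"flat"` uses 1/k, `"given"` uses `root_pi`.
#' @param condition_survival Divide the likelihood by the probability that
#'   both crown lineages survive to the present,
#'   \eqn{\sum_i \pi_i \lambda_i (1 - E_i)^2} (default `TRUE`).
#' @param root_pi Root state probabilities when `root_mode = "given"`.
#' @param rtol,atol Relative/absolute tolerance of the adaptive
#'   Dormand-Prince integrator used along each branch.
#' @return A list of class `sse_options`.
#' @export
sse_options <- function(root_mode = c("fitzjohn", "flat", "given"),
                        condition_survival = TRUE, root_pi = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  root_mode <- match.arg(root_mode)
  if (root_mode == "given" && is.null(root_pi))
    stop_reefdiv("root_mode 'given' needs root_pi")
  structure(list(root_mode = root_mode,
                 condition_survival = condition_survival,
                 root_pi = root_pi, rtol = rtol, atol = atol),
            class = "sse_options")
}

## shared preparation for the compiled pruning pass
musse_prep <- function(tree, states, k, options) {
  if (is.null(tree$edge.length)) stop_reefdiv("tree has no branch lengths")
  if (!ape::is.binary.phylo(tree) || !ape::is.rooted(tree))
    stop_reefdiv("SSE likelihood requires a rooted, strictly binary tree")
  tr <- ape::reorder.phylo(tree, "postorder")
  tipD <- tip_state_matrix(tr, states, k)
  rm_code <- match(options$root_mode, c("fitzjohn", "flat", "given"))
  pi_given <- options$root_pi %||% rep(1 / k, k)
  if (abs(sum(pi_given) - 1) > 1e-8)
    stop_reefdiv("root_pi must sum to 1")
  list(tr = tr, tipD = tipD, rm_code = rm_code, pi_given = pi_given)
}

#' MuSSE log-likelihood
#'
#' Computes the log-likelihood of tip character data under a multi-state
#' speciation-extinction (MuSSE) model by pruning: along every branch the
#' coupled ODEs for the extinction probability \eqn{E_i(t)} and the data
#' partial likelihood \eqn{D_i(t)} are integrated tipward to rootward
#' with an adaptive Dormand-Prince stepper, daughters are merged at nodes
#' with a factor \eqn{\lambda_i}, and the root is treated according to
#' `options`. Partial likelihoods are renormalised per branch with the
#' log scaler accumulated, so large trees do not underflow. Sampling is
#' assumed complete (every extant tip in the clade is in the tree).
#'
#' @param tree Rooted, strictly binary `phylo` with branch lengths (Myr).
#' @param states A [tip_state_map], or a named integer vector of observed
#'   tip states; ambiguous tips may list several admissible states.
#' @param params An [sse_params] object.
#' @param options An [sse_options] object.
#' @return The log-likelihood (finite for valid inputs; `-Inf` when the
#'   data have probability zero under `params`, e.g. a required
#'   transition with rate zero).
#' @examples
#' p <- sse_params(lam = c(0.2, 0.2), mu = c(0, 0), Q = 0.05)
#' sim <- simulate_mbd_tree(p, n_extant = 10, seed = 4)
#' musse_loglik(sim$tree, sim$states, p)
#' @export
musse_loglik <- function(tree, states, params, options = sse_options()) {
  params <- validate_sse_params(params)
  pp <- musse_prep(tree, states, params$k, options)
  musse_loglik_cpp(pp$tr$edge, pp$tr$edge.length, length(pp$tr$tip.label),
                   pp$tipD, params$lam, params$mu, params$Q, pp$rm_code,
                   pp$pi_given, options$condition_survival, options$rtol,
                   options$atol)
}
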