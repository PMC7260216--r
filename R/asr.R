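#' Marginal ancestral-state reconstruction under MuSSE
#'
#' For every node of the tree, the marginal probability of each character
#' state is the full-tree likelihood with that node's state clamped,
#' renormalised over states. The implementation reuses the cached
#' pruning partials: for each node it re-propagates only the node-to-root
#' path, which is mathematically identical to the brute-force
#' clamp-and-recompute but linear rather than quadratic in tree size.
#' The root is treated according to `options$root_mode`, consistently
#' with [musse_loglik].
#'
#' @param tree Rooted binary `phylo` with branch lengths.
#' @param states Tip states (see [tip_state_map]); ambiguous tips get
#'   marginals over their admissible states, observed tips keep
#'   probability 1 on the observed state.
#' @param params An [sse_params], typically from a converged fit.
#' @param options An [sse_options].
#' @return A `node_marginals` object: matrix with one row per node id
#'   (ape numbering of the reordered tree: tips `1..ntip`, root
#'   `ntip+1`), one column per state; rows sum to 1. The (re-ordered)
#'   tree is attached as attribute `"tree"`.
#' @examples
#' p <- sse_params(c(0.2, 0.2), c(0, 0), 0.1)
#' sim <- simulate_mbd_tree(p, n_extant = 8, seed = 3)
#' asr <- marginal_asr(sim$tree, sim$states, p)
#' head(asr)
#' @export
marginal_asr <- function(tree, states, params, options = sse_options()) {
  params <- validate_sse_params(params)
  pp <- musse_prep(tree, states, params$k, options)
  m <- musse_marginals_cpp(pp$tr$edge, pp$tr$edge.length,
                           length(pp$tr$tip.label), pp$tipD, params$lam,
                           params$mu, params$Q, pp$rm_code, pp$pi_given,
                           options$condition_survival, options$rtol,
                           options$atol)
  colnames(m) <- params$states
  bad <- abs(rowSums(m) - 1) > 1e-9
  if (any(bad))
    stop_reefdiv("marginals failed to normalise at node(s) %s",
                 paste(head(which(bad), 5), collapse = ", "))
  structure(m, class = c("node_marginals", class(m)), tree = pp$tr,
            params = params)
}

#' Write / read node marginals as TSV
#'
#' Columns: `node`, `p_<state>` for each state. Node ids follow the ape
#' numbering of the tree attached to the marginals.
#'
#' @param marginals A `node_marginals` object (for writing) or path.
#' @param path Output path.
#' @export
write_marginals <- function(marginals, path) {
  d <- data.frame(node = seq_len(nrow(marginals)), unclass(marginals)[,])
  names(d)[-1] <- paste0("p_", colnames(marginals))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marginals
#' @export
read_marginals <- function(path) {
  d <- read.delim(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  colnames(m) <- sub("^p_", "", colnames(m))
  m[order(d$node), , drop = FALSE]
}
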