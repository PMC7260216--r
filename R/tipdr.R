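#' Equal-splits measure for one tip
#'
#' The equal-splits value of tip i is
#' \deqn{ES_i = \sum_{j=1}^{N_i} l_j \, 2^{-(j-1)}}
#' where \eqn{l_1} is the tip's pendant edge and j indexes the edges along
#' the tip-to-root path. Each successive split toward the root halves the
#' weight, apportioning the tree's branch lengths "equally" among the tips
#' that share them. Units are Myr when branch lengths are in Myr.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @param tip Tip label (or index).
#' @return The ES value (Myr). Zero-length pendant edges are fine as long
#'   as the whole path is not of length zero.
#' @export
equal_splits <- function(tree, tip) {
  if (is.character(tip)) {
    i <- match(tip, tree$tip.label)
    if (is.na(i)) stop_reefdiv("unknown tip label: %s", tip)
  } else {
    i <- as.integer(tip)
    if (i < 1 || i > length(tree$tip.label)) stop_reefdiv("tip index out of range")
  }
  parent <- integer(max(tree$edge))
  elen_to <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen_to[tree$edge[, 2]] <- tree$edge.length
  es <- 0
  w <- 1
  node <- i
  while (parent[node] != 0L) {
    es <- es + w * elen_to[node]
    w <- w / 2
    node <- parent[node]
  }
  if (es <= 0) stop_reefdiv("equal-splits undefined: zero-length path for tip %s",
                            tree$tip.label[i])
  es
}

#' DR tip speciation-rate statistic
#'
#' The DR statistic of a tip is the inverse of its equal-splits measure,
#' \eqn{DR_i = 1 / ES_i} (per Myr). Tips sitting on short, recently and
#' repeatedly split paths get high values; isolated tips on long pendant
#' branches get low values. DR is a fast proxy for the recent speciation
#' rate of each terminal lineage; it is not a net-diversification
#' estimate, and output is labelled accordingly.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Named numeric vector of per-tip rates (per Myr), in
#'   `tree$tip.label` order; all values are positive. Rotating or
#'   ladderizing the tree does not change any value, and rescaling all
#'   branch lengths by c divides every value by c.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' dr_statistic(tr)  # 2/3 for every tip
#' @export
dr_statistic <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  parent <- integer(nnode)
  elen_to <- numeric(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen_to[tree$edge[, 2]] <- tree$edge.length
  out <- numeric(ntip)
  for (i in seq_len(ntip)) {
    es <- 0; w <- 1; node <- i
    while (parent[node] != 0L) {
      es <- es + w * elen_to[node]
      w <- w / 2
      node <- parent[node]
    }
    if (es <= 0)
      stop_reefdiv("equal-splits undefined: zero-length path for tip %s",
                   tree$tip.label[i])
    out[i] <- 1 / es
  }
  names(out) <- tree$tip.label
  out
}

#' Pool per-tip rates across a tree set by the median
#'
#' Given per-tip rate vectors estimated on each tree of a set (all sharing
#' one tip-label set), returns the per-tree columns together with the
#' row-wise median, the pooled tip-rate estimate used as the response of
#' the predictive stage.
#'
#' @param tables List of named numeric vectors (one per tree), identical
#'   label sets.
#' @return Data frame with `tip`, one `tree<i>` column per input, and
#'   `median`.
#' @export
pool_median <- function(tables) {
  stopifnot(length(tables) >= 1)
  labs <- names(tables[[1]])
  for (i in seq_along(tables)) {
    di <- setdiff(union(names(tables[[i]]), labs),
                  intersect(names(tables[[i]]), labs))
    if (length(di))
      stop_reefdiv("tip-label mismatch in table %d: %s", i,
                   paste(head(di, 10), collapse = ", "))
  }
  m <- vapply(tables, function(x) unname(x[labs]), numeric(length(labs)))
  m <- matrix(m, nrow = length(labs))
  out <- data.frame(tip = labs, m)
  names(out)[-1] <- paste0("tree", seq_along(tables))
  out$median <- apply(m, 1, median)
  out
}

#' Read externally computed tip rates
#'
#' Accepts any per-tip rate table in the same TSV schema the package
#' writes (columns `tip`, one or more rate columns, optionally `median`),
#' so rates estimated by other programs (e.g. Bayesian rate-shift
#' methods) can be plugged into the predictive stage in place of DR.
#'
#' @param path Path to a tab-separated file with a header.
#' @return Data frame with a `median` column (computed if absent).
#' @export
read_tip_rates <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  if (!"tip" %in% names(d)) stop_reefdiv("tip-rate file needs a 'tip' column")
  ratecols <- setdiff(names(d), c("tip", "median"))
  if (!length(ratecols)) stop_reefdiv("tip-rate file has no rate columns")
  if (!"median" %in% names(d))
    d$median <- apply(as.matrix(d[ratecols]), 1, median)
  d
}
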