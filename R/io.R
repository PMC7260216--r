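#' Read and write trees, tip states and trait tables
#'
#' Thin, validated wrappers over the standard formats: Newick for trees
#' (via ape), tab-separated tables with a header for tip states, tip
#' rates and traits, JSON for fits and manifests. Round-trips preserve
#' topology, labels and branch lengths to 1e-9.
#'
#' @param path File path.
#' @return `read_newick` returns a `phylo`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stop_reefdiv("malformed Newick in %s", path)
  if (anyDuplicated(tr$tip.label))
    stop_reefdiv("duplicate tip labels in %s: %s", path,
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", "))
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname read_newick
#' @param states A [tip_state_map] or named state vector. Ambiguous
#'   state sets are written comma-separated.
#' @export
write_tip_states <- function(states, path) {
  d <- data.frame(tip = names(states),
                  state = vapply(states, paste, "", collapse = ","))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_newick
#' @param k Number of states.
#' @export
read_tip_states <- function(path, k) {
  d <- read.delim(path, colClasses = c("character", "character"))
  sets <- lapply(strsplit(d$state, ","), as.integer)
  names(sets) <- d$tip
  tip_state_map(sets, k)
}

#' @rdname read_newick
#' @param table Trait table data frame.
#' @export
write_trait_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_newick
#' @export
read_trait_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  for (v in intersect(CATEGORICAL, names(d))) d[[v]] <- factor(d[[v]])
  d
}

## ---- segment-annotated Newick --------------------------------------------
## Each edge carries a comment [&map=s1:d1|s2:d2|...] after its branch
## length, segments in root-to-tip order. The reader understands files
## written by this writer (comments are matched to edges by the writer's
## left-to-right postorder token layout).

#' Write a character history as segment-annotated Newick
#'
#' @param history A `character_history`.
#' @param path Output path.
#' @export
write_history_newick <- function(history, path) {
  tr <- history$tree
  ntip <- length(tr$tip.label)
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  seg_str <- function(e) {
    s <- history$edge_segments[[e]]
    paste(sprintf("%d:%.15g", s$state, s$duration), collapse = "|")
  }
  rec <- function(node) {
    below <- kids[[as.character(node)]]
    inner <- if (is.null(below)) tr$tip.label[node] else
      paste0("(", paste(vapply(below, function(e)
        paste0(rec(tr$edge[e, 2]),
               sprintf(":%.15g[&map=%s]", tr$edge.length[e], seg_str(e))),
        ""), collapse = ","), ")")
    inner
  }
  root <- ntip + 1L
  txt <- paste0(rec(root), ";")
  if (!is.null(history$root_edge_segments)) {
    s <- history$root_edge_segments
    txt <- paste0(sub(";$", "", txt),
                  sprintf(":%.15g[&map=%s];", sum(s$duration),
                          paste(sprintf("%d:%.15g", s$state, s$duration),
                                collapse = "|")))
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read a segment-annotated Newick history
#'
#' @param path Path to a file written by [write_history_newick].
#' @return A `character_history`.
#' @export
read_history_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  comments <- regmatches(txt, gregexpr("\\[&map=[^]]*\\]", txt))[[1]]
  plain <- gsub("\\[&[^]]*\\]", "", txt)
  tr <- ape::read.tree(text = plain)
  if (is.null(tr)) stop_reefdiv("malformed annotated Newick in %s", path)
  parse_segs <- function(cm) {
    body <- sub("^\\[&map=", "", sub("\\]$", "", cm))
    parts <- strsplit(strsplit(body, "|", fixed = TRUE)[[1]], ":")
    data.frame(state = as.integer(vapply(parts, `[`, "", 1)),
               duration = as.numeric(vapply(parts, `[`, "", 2)))
  }
  ## edge order as laid out by the writer: left-to-right postorder
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  order_out <- integer(0)
  walk <- function(node) {
    below <- kids[[as.character(node)]]
    for (e in below) {
      child <- tr$edge[e, 2]
      if (!is.null(kids[[as.character(child)]])) walk(child)
      order_out <<- c(order_out, e)
    }
  }
  walk(length(tr$tip.label) + 1L)
  has_root_edge <- length(comments) == nrow(tr$edge) + 1L
  segs <- vector("list", nrow(tr$edge))
  for (i in seq_along(order_out))
    segs[[order_out[i]]] <- parse_segs(comments[i])
  node_states <- integer(max(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    s <- segs[[e]]
    node_states[tr$edge[e, 1]] <- s$state[1]
    node_states[tr$edge[e, 2]] <- s$state[nrow(s)]
  }
  root_segs <- if (has_root_edge) parse_segs(comments[length(comments)]) else NULL
  character_history(tr, segs, node_states, root_edge_segments = root_segs)
}

## walk order helper used by the annotated-newick reader is postorder in
## the stored child order; exposed nowhere.

#' Write an SSE fit (or posterior summary) as JSON
#'
#' @param fit An `sse_fit` or the data frame from [pool_and_summarize].
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  if (inherits(fit, "sse_fit")) {
    obj <- list(k = fit$k, lam = fit$params$lam, mu = fit$params$mu,
                Q = fit$params$Q, states = fit$params$states,
                loglik = fit$loglik, converged = fit$converged,
                root_mode = fit$options$root_mode,
                condition_survival = fit$options$condition_survival)
  } else {
    obj <- fit
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write posterior draws as TSV (one row per draw)
#'
#' @param draws A `posterior_draws` object or list of them.
#' @param path Output path.
#' @export
write_draws_tsv <- function(draws, path) {
  if (inherits(draws, "posterior_draws")) draws <- list(draws)
  d <- do.call(rbind, lapply(draws, function(x)
    data.frame(tree = x$tree_id, x$draws, check.names = FALSE)))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
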