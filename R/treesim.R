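#' Simulate a phylogeny under a multi-state birth-death process
#'
#' Forward (Gillespie) simulation of a k-state speciation-extinction
#' process: each lineage in state s speciates at rate \eqn{\lambda_s},
#' goes extinct at rate \eqn{\mu_s} and changes character state at rates
#' \eqn{q_{sj}}. Waiting times are exact exponentials; there is no time
#' discretisation. The full (unpruned) tree, the true piecewise-constant
#' character history along every edge and the exact transition counts are
#' all returned, so downstream inference can be validated against the
#' generating truth.
#'
#' Stopping is either at a fixed `max_time` (all lineages alive at that
#' time become extant tips; total extinction is a legitimate outcome and
#' is returned, not retried) or at a fixed number of extant tips
#' `n_extant` (the simulation stops at the first moment the extant count
#' reaches the target; runs that die out first are restarted up to
#' `max_retries` times).
#'
#' @param params An [sse_params] object.
#' @param root_state Integer state at the root (default 1).
#' @param max_time Stop time in Myr (exclusive with `n_extant`).
#' @param n_extant Target number of surviving tips (exclusive with
#'   `max_time`); must exceed the number of starting lineages.
#' @param seed Integer seed; identical seed and inputs reproduce the
#'   outcome bit-for-bit.
#' @param start `"crown"` (default; two lineages in the root state, the
#'   usual conditioning of SSE likelihoods) or `"stem"` (one lineage; the
#'   pre-speciation stem is returned as `root.edge` with its own history
#'   segments).
#' @param max_retries Restart budget for `n_extant` runs that go extinct.
#' @return A `sim_outcome` list: `tree` (extant-only `phylo`, `NULL` when
#'   fewer than 2 lineages survive), `states` (a [tip_state_map] of true
#'   extant tip states), `full_tree` (`phylo` including extinct tips),
#'   `history` (a `character_history` on `full_tree`), `true_transitions`
#'   (k x k integer counts, zero diagonal), `n_extant`, `seed`, `params`.
#' @examples
#' p <- sse_params(lam = c(0.3, 0.3), mu = c(0.05, 0.05), Q = 0.05)
#' out <- simulate_mbd_tree(p, n_extant = 30, seed = 1)
#' out$n_extant
#' @export
simulate_mbd_tree <- function(params, root_state = 1, max_time = NULL,
                              n_extant = NULL, seed = NULL,
                              start = c("crown", "stem"),
                              max_retries = 1000) {
  params <- validate_sse_params(params)
  start <- match.arg(start)
  if (is.null(max_time) == is.null(n_extant))
    stop_reefdiv("give exactly one of max_time or n_extant")
  if (!is.null(max_time) && max_time <= 0)
    stop_reefdiv("max_time must be positive")
  n_start <- if (start == "crown") 2L else 1L
  if (!is.null(n_extant) && n_extant <= n_start)
    stop_reefdiv("n_extant must exceed the %d starting lineage(s)", n_start)
  if (root_state < 1 || root_state > params$k)
    stop_reefdiv("root_state out of range")
  if (!is.null(seed)) set.seed(seed)

  retries <- 0L
  repeat {
    raw <- sim_mbd_core(params, root_state, max_time, n_extant, n_start)
    if (!is.null(n_extant) && raw$n_extant < n_extant) {
      retries <- retries + 1L
      if (retries > max_retries)
        stop_reefdiv(
          "clade died: total extinction in every one of %d attempts",
          retries, class = "reefdiv_clade_died")
      next
    }
    break
  }
  out <- build_sim_outcome(raw, params, start)
  out$seed <- seed
  out$retries <- retries
  out
}

## Event-driven core. Returns raw per-lineage records.
sim_mbd_core <- function(params, root_state, max_time, n_extant, n_start) {
  k <- params$k
  lam <- params$lam; mu <- params$mu; Q <- params$Q
  qoff <- Q; diag(qoff) <- 0
  qs <- rowSums(qoff)
  totrate <- lam + mu + qs

  cap <- 64L
  l_state <- integer(cap); l_birth <- numeric(cap); l_parent <- integer(cap)
  l_fate <- integer(cap)  # 0 active, 1 extant tip, 2 extinct, 3 internal
  l_end <- numeric(cap)
  l_segs <- vector("list", cap)   # per lineage: matrix cols (state, t_start)
  n_lin <- 0L
  trans <- matrix(0L, k, k)

  grow <- function() {
    cap2 <- 2L * cap
    length(l_state) <<- cap2; length(l_birth) <<- cap2
    length(l_parent) <<- cap2; length(l_fate) <<- cap2
    length(l_end) <<- cap2; length(l_segs) <<- cap2
    cap <<- cap2
  }
  add_lineage <- function(st, tm, par) {
    n_lin <<- n_lin + 1L
    if (n_lin > cap) grow()
    l_state[n_lin] <<- st; l_birth[n_lin] <<- tm
    l_parent[n_lin] <<- par; l_fate[n_lin] <<- 0L
    l_segs[[n_lin]] <<- matrix(c(st, tm), 1, 2)
    n_lin
  }

  for (i in seq_len(n_start)) add_lineage(root_state, 0, 0L)
  active <- seq_len(n_start)
  t <- 0

  repeat {
    rates <- totrate[l_state[active]]
    R <- sum(rates)
    if (R <= 0) {  # absorbing: e.g. pure-birth rate 0; only max_time valid
      t_next <- Inf
    } else {
      t_next <- t + rexp(1L, R)
    }
    if (!is.null(max_time) && t_next > max_time) {
      l_fate[active] <- 1L
      l_end[active] <- max_time
      break
    }
    if (is.infinite(t_next))
      stop_reefdiv("all rates zero before reaching the stop condition")
    t <- t_next
    li <- if (length(active) == 1L) active else
      active[sample.int(length(active), 1L, prob = rates)]
    s <- l_state[li]
    u <- runif(1L) * totrate[s]
    if (u < lam[s]) {
      ## speciation
      l_fate[li] <- 3L
      l_end[li] <- t
      c1 <- add_lineage(s, t, li)
      c2 <- add_lineage(s, t, li)
      active <- c(setdiff(active, li), c1, c2)
      if (!is.null(n_extant) && length(active) == n_extant) {
        l_fate[active] <- 1L
        l_end[active] <- t
        break
      }
    } else if (u < lam[s] + mu[s]) {
      ## extinction
      l_fate[li] <- 2L
      l_end[li] <- t
      active <- setdiff(active, li)
      if (length(active) == 0L) break
    } else {
      ## character transition
      j <- sample.int(k, 1L, prob = qoff[s, ])
      trans[s, j] <- trans[s, j] + 1L
      l_state[li] <- j
      l_segs[[li]] <- rbind(l_segs[[li]], c(j, t))
    }
  }

  idx <- seq_len(n_lin)
  list(state = l_state[idx], birth = l_birth[idx], parent = l_parent[idx],
       fate = l_fate[idx], end = l_end[idx], segs = l_segs[idx],
       n_extant = sum(l_fate[idx] == 1L), trans = trans,
       root_state = root_state)
}

## Assemble phylo trees + history from the raw lineage records.
build_sim_outcome <- function(raw, params, start) {
  n_lin <- length(raw$state)
  is_tip <- raw$fate %in% c(1L, 2L)
  tips <- which(is_tip)
  ntip <- length(tips)

  full_tree <- NULL
  history <- NULL
  stem_segments <- NULL
  root_lineage <- which(raw$parent == 0L)

  if (ntip >= 2L) {
    ## stem start: the initial lineage's pre-speciation part becomes the
    ## root edge; its end node is the root of the binary tree.
    node_of <- integer(n_lin)  # end-node id per lineage
    tip_ids <- seq_len(ntip)
    node_of[tips] <- tip_ids
    internals <- which(raw$fate == 3L)
    if (start == "crown") {
      root_id <- ntip + 1L
      node_of[internals] <- ntip + 1L + seq_along(internals)
      edge_lineages <- seq_len(n_lin)
    } else {
      stem <- root_lineage
      root_id <- ntip + 1L
      node_of[stem] <- root_id
      rest <- setdiff(internals, stem)
      node_of[rest] <- ntip + 1L + seq_along(rest)
      edge_lineages <- setdiff(seq_len(n_lin), stem)
      stem_segments <- segments_of(raw, stem)
    }
    pl <- raw$parent[edge_lineages]
    parent_node <- integer(length(edge_lineages))
    parent_node[pl == 0L] <- root_id
    parent_node[pl != 0L] <- node_of[pl[pl != 0L]]
    edge <- cbind(parent_node, node_of[edge_lineages])
    elen <- raw$end[edge_lineages] - raw$birth[edge_lineages]
    lab_ext <- cumsum(raw$fate[tips] == 1L)
    lab_dead <- cumsum(raw$fate[tips] == 2L)
    tip_label <- ifelse(raw$fate[tips] == 1L, paste0("t", lab_ext),
                        paste0("x", lab_dead))
    full_tree <- structure(
      list(edge = unname(edge), edge.length = unname(elen),
           tip.label = tip_label, Nnode = max(node_of) - ntip),
      class = "phylo", order = "cladewise")
    if (start == "stem")
      full_tree$root.edge <- raw$end[root_lineage] - raw$birth[root_lineage]
    full_tree <- ape::reorder.phylo(full_tree, "cladewise")

    edge_segments <- lapply(seq_len(nrow(full_tree$edge)), function(e) {
      segments_of(raw, edge_lineages[match_edge(edge, full_tree$edge[e, ])])
    })
    node_states <- integer(max(node_of))
    node_states[node_of[tips]] <- raw$state[tips]
    node_states[node_of[raw$fate == 3L]] <- raw$state[raw$fate == 3L]
    if (start == "crown") node_states[root_id] <- raw$root_state
    history <- character_history(full_tree, edge_segments, node_states,
                                 root_edge_segments = stem_segments)
  }

  extant <- which(raw$fate == 1L)
  tree <- NULL
  states <- NULL
  if (length(extant) >= 2L) {
    keep <- paste0("t", seq_len(length(extant)))
    tree <- ape::keep.tip(full_tree, keep)
    tree$root.edge <- NULL
    st <- raw$state[extant]
    names(st) <- keep
    states <- tip_state_map(st, params$k)
  }

  structure(list(tree = tree, states = states, full_tree = full_tree,
                 history = history, true_transitions = raw$trans,
                 n_extant = length(extant), params = params, start = start),
            class = "sim_outcome")
}

match_edge <- function(edge, row) which(edge[, 1] == row[1] & edge[, 2] == row[2])

segments_of <- function(raw, li) {
  m <- raw$segs[[li]]
  t_start <- m[, 2]
  t_end <- c(m[-1, 2], raw$end[li])
  data.frame(state = as.integer(m[, 1]), duration = t_end - t_start)
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf("Multi-state birth-death simulation: %d extant tip(s), k = %d\n",
              x$n_extant, x$params$k))
  if (!is.null(x$full_tree))
    cat(sprintf("  full tree: %d tips (%d extinct)\n",
                length(x$full_tree$tip.label),
                length(x$full_tree$tip.label) - x$n_extant))
  cat(sprintf("  true transitions: %d\n", sum(x$true_transitions)))
  invisible(x)
}

#' Character history on a phylogeny
#'
#' A per-edge piecewise-constant record of character state: for every edge
#' of `tree` (by row of `tree$edge`), an ordered root-to-tip data frame of
#' `(state, duration)` segments, plus the state at every node. Segment
#' durations along an edge sum to the branch length; the first segment
#' matches the parent node's state and the last the child's.
#'
#' @param tree A `phylo` object.
#' @param edge_segments List (one per edge row) of data frames with
#'   columns `state`, `duration`.
#' @param node_states Integer vector of states indexed by node id.
#' @param root_edge_segments Optional segments for a stem (root) edge.
#' @return An object of class `character_history`.
#' @export
character_history <- function(tree, edge_segments, node_states,
                              root_edge_segments = NULL) {
  if (length(edge_segments) != nrow(tree$edge))
    stop_reefdiv("need one segment list per edge")
  for (e in seq_along(edge_segments)) {
    seg <- edge_segments[[e]]
    if (abs(sum(seg$duration) - tree$edge.length[e]) >
        1e-9 * max(1, tree$edge.length[e]))
      stop_reefdiv("segment durations on edge %d do not sum to its length", e)
    if (seg$state[1] != node_states[tree$edge[e, 1]])
      stop_reefdiv("first segment state on edge %d differs from parent node", e)
    if (seg$state[nrow(seg)] != node_states[tree$edge[e, 2]])
      stop_reefdiv("last segment state on edge %d differs from child node", e)
    if (nrow(seg) > 1 && any(diff(seg$state) == 0))
      stop_reefdiv("consecutive identical states on edge %d", e)
  }
  structure(list(tree = tree, edge_segments = edge_segments,
                 node_states = node_states,
                 root_edge_segments = root_edge_segments),
            class = "character_history")
}

#' @export
print.character_history <- function(x, ...) {
  nev <- sum(vapply(x$edge_segments, nrow, 1L) - 1L)
  cat(sprintf("Character history on %d edges: %d state change(s)\n",
              length(x$edge_segments), nev))
  invisible(x)
}

#' Simulate a set of independent trees
#'
#' Emulates a tree-ensemble analysis (e.g. a distribution of 100
#' near-complete trees) by simulating `n_trees` independent replicates
#' under one parameter set. Per-tree seeds are derived deterministically
#' from the master seed, so the set is reproducible as a whole and each
#' tree is reproducible on its own.
#'
#' @inheritParams simulate_mbd_tree
#' @param n_trees Number of trees (>= 1).
#' @return List of `sim_outcome` objects.
#' @export
simulate_tree_set <- function(params, root_state = 1, max_time = NULL,
                              n_extant = NULL, n_trees, seed = NULL,
                              start = c("crown", "stem"),
                              max_retries = 1000) {
  stopifnot(n_trees >= 1)
  start <- match.arg(start)
  seed <- seed %||% 1L
  lapply(seq_len(n_trees), function(i) {
    tryCatch(
      simulate_mbd_tree(params, root_state, max_time, n_extant,
                        seed = derive_seed(seed, paste0("tree:", i)),
                        start = start, max_retries = max_retries),
      reefdiv_clade_died = function(e)
        stop_reefdiv("replicate %d: %s", i, conditionMessage(e),
                     class = "reefdiv_clade_died"))
  })
}

GUILDS <- c("GC", "MI", "OM", "PK", "SI", "HD")

#' Specification for a synthetic species trait table
#'
#' Declares the generator for a synthetic stand-in of a reef-fish style
#' trait table: six trophic guilds (GC generalized carnivores, MI mobile
#' invertivores, OM omnivores, PK planktivores, SI sessile invertivores,
#' HD herbivores/detritivores), lognormal maximum body length, and eight
#' further ecological/geographical predictors drawn independently from
#' documented distributions. A latent per-species diversification rate is
#' `rate_fn(guild, size)` times multiplicative gamma noise with mean 1 and
#' shape `noise_shape`, so the signal a predictive model should recover is
#' known exactly.
#'
#' @param n_species Number of species rows.
#' @param guild_probs Probabilities over the six guilds (order GC, MI, OM,
#'   PK, SI, HD); must sum to 1.
#' @param size_log_mean,size_log_sd Lognormal parameters for maximum body
#'   length in cm (defaults give a median of 15 cm).
#' @param rate_fn Vectorised function `(guild, size) -> expected rate`
#'   (per Myr, all values > 0).
#' @param noise_shape Gamma shape of the multiplicative rate noise; large
#'   values approach noise-free rates.
#' @param seed Integer seed.
#' @return A `trait_gen_spec` list.
#' @export
trait_gen_spec <- function(n_species, guild_probs = rep(1 / 6, 6),
                           size_log_mean = log(15), size_log_sd = 0.9,
                           rate_fn = default_rate_fn,
                           noise_shape = 4, seed = 1L) {
  stopifnot(n_species >= 1, length(guild_probs) == 6)
  if (abs(sum(guild_probs) - 1) > 1e-12)
    stop_reefdiv("guild_probs must sum to 1")
  if (noise_shape <= 0) stop_reefdiv("noise_shape must be > 0")
  structure(list(n_species = as.integer(n_species),
                 guild_probs = guild_probs, size_log_mean = size_log_mean,
                 size_log_sd = size_log_sd, rate_fn = rate_fn,
                 noise_shape = noise_shape, seed = as.integer(seed)),
            class = "trait_gen_spec")
}

#' Default guild-and-size rate function
#'
#' Herbivores/detritivores diversify fastest, with the rate rising in
#' body size; other guilds have flat or gently size-dependent rates.
#' Values are per Myr and loosely bracket the magnitudes typical of
#' recent fish tip rates (~0.05-0.25).
#'
#' @param guild Character vector of guild codes.
#' @param size Numeric body lengths (cm).
#' @return Expected diversification rates, same length as `guild`.
#' @export
default_rate_fn <- function(guild, size) {
  base <- c(GC = 0.07, MI = 0.07, OM = 0.09, PK = 0.09, SI = 0.08,
            HD = 0.10)[guild]
  slope <- ifelse(guild == "HD", 0.35, 0.05)
  unname(base * (1 + slope * log(pmax(size, 1) / 15)))
}

#' Generate a synthetic trait table with known true rates
#'
#' Draws a species table with all ten predictor columns (trophic guild,
#' body size, activity, water-column position, range size as occupied-cell
#' count, ocean basin, absolute centroid latitude, distance to the
#' Indo-Australian Archipelago, mean SST, mean primary productivity) and
#' latent true diversification rates from the declared generator. Only
#' guild and size carry rate signal; the geographical columns are
#' independent noise by construction, which is what lets attribution
#' methods be benchmarked against a known answer.
#'
#' @param spec A [trait_gen_spec].
#' @return List with `table` (data frame, one row per species) and
#'   `true_rates` (named numeric, per Myr).
#' @export
simulate_trait_table <- function(spec) {
  stopifnot(inherits(spec, "trait_gen_spec"))
  set.seed(spec$seed)
  n <- spec$n_species
  guild <- sample(GUILDS, n, replace = TRUE, prob = spec$guild_probs)
  size <- rlnorm(n, spec$size_log_mean, spec$size_log_sd)
  expected <- spec$rate_fn(guild, size)
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop_reefdiv("rate_fn produced non-positive or non-finite rates")
  noise <- rgamma(n, shape = spec$noise_shape, rate = spec$noise_shape)
  rates <- expected * noise
  tab <- data.frame(
    species = paste0("s", seq_len(n)),
    trophic = factor(guild, levels = GUILDS),
    size = size,
    activity = factor(sample(c("diurnal", "nocturnal", "both"), n, TRUE,
                             prob = c(0.60, 0.25, 0.15)),
                      levels = c("diurnal", "nocturnal", "both")),
    position = factor(sample(c("benthic", "benthopelagic", "pelagic"), n,
                             TRUE, prob = c(0.55, 0.30, 0.15)),
                      levels = c("benthic", "benthopelagic", "pelagic")),
    range = 1L + rnbinom(n, size = 0.7, mu = 60),
    basin = factor(sample(c("Atlantic", "Indo-Pacific", "both"), n, TRUE,
                          prob = c(0.20, 0.65, 0.15)),
                   levels = c("Atlantic", "Indo-Pacific", "both")),
    abs_lat = pmin(abs(rnorm(n, 0, 12)), 60),
    dist_iaa = pmin(rlnorm(n, log(6000), 0.9), 20015),
    sst = rnorm(n, 27, 2),
    prprod = rlnorm(n, log(500), 0.5),
    stringsAsFactors = FALSE)
  names(rates) <- tab$species
  list(table = tab, true_rates = rates)
}
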