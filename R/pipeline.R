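#' Configuration for the end-to-end synthetic analysis
#'
#' Declares every stage of the workflow: simulate a tree set under a
#' multi-state birth-death process, estimate DR tip rates and pool them,
#' attach a synthetic trait table whose trophic column is the true tip
#' state, attribute rate variation with the boosting protocol, fit MuSSE
#' by maximum likelihood and sample its posterior per tree, pool draws,
#' reconstruct ancestral states, draw stochastic maps and count
#' transitions. Every stage consumes only its own sub-configuration and
#' all randomness derives from the single master `seed`.
#'
#' @param seed Master seed.
#' @param n_trees Number of simulated trees.
#' @param n_extant Tips per tree.
#' @param lam,mu Per-state speciation/extinction rates.
#' @param q Transition rate (scalar symmetric) or k x k matrix.
#' @param guilds Guild label per state (length k); these become the
#'   `trophic` levels of the trait tables.
#' @param root_state Root character state.
#' @param mcmc MCMC settings: `n_gen`, `n_prelim`, `burn_frac`.
#' @param n_maps Stochastic maps per tree.
#' @param boost Boosting settings passed to [boost_spec] (reduced
#'   defaults suitable for a smoke run; raise `n_boot`/`cv_reps` for a
#'   full analysis).
#' @param filter Optional predicate `function(table) -> logical` row
#'   filter applied to the modelling table before the boosting stage
#'   (the hook for sensitivity reruns such as restricting families).
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_trees = 3, n_extant = 80,
                       lam = c(0.2, 0.1), mu = c(0.03, 0.03), q = 0.02,
                       guilds = NULL, root_state = 1,
                       mcmc = list(n_gen = 500, n_prelim = 50,
                                   burn_frac = 0.1),
                       n_maps = 10,
                       boost = list(n_boot = 25, cv_reps = 25, n_draws = 20,
                                    nrounds = 60,
                                    grid = list(eta = c(0.05, 0.1),
                                                max_depth = c(3, 5),
                                                gamma = 0,
                                                subsample = c(0.75, 1))),
                       filter = NULL, out_dir = NULL) {
  k <- length(lam)
  guilds <- guilds %||% GUILDS[seq_len(k)]
  if (length(guilds) != k) stop_reefdiv("need one guild label per state")
  params <- sse_params(lam, mu, q, states = guilds)
  structure(list(seed = as.integer(seed), n_trees = n_trees,
                 n_extant = n_extant, params = params,
                 root_state = root_state, mcmc = mcmc, n_maps = n_maps,
                 boost = boost, filter = filter, out_dir = out_dir),
            class = "run_config")
}

## synthetic trait rows for one simulated tree: trophic is the TRUE tip
## state; the other nine columns are drawn independently (no rate signal)
trait_table_for_tree <- function(sim, guilds, seed) {
  tips <- names(sim$states)
  n <- length(tips)
  spec <- trait_gen_spec(n, seed = seed)
  tab <- simulate_trait_table(spec)$table
  tab$species <- tips
  st <- vapply(sim$states, `[`, 1L, 1)
  tab$trophic <- factor(guilds[st], levels = sort(unique(guilds)))
  tab
}

#' Run the full synthetic analysis pipeline
#'
#' Executes all stages in dependency order and, when `out_dir` is set,
#' writes each stage's outputs (Newick trees, TSV tables, JSON
#' summaries) plus a run manifest with the config echo, package version,
#' file hashes and per-stage wall-clock times. Identical configs produce
#' bit-identical outputs.
#'
#' @param config A [run_config].
#' @return List with elements `trees`, `tip_rates`, `boost`, `sse`,
#'   `transitions` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- proc.time()[3]
  stages <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  tick <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop_reefdiv("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)))
    stages[[name]] <<- proc.time()[3] - t0
    val
  }
  k <- config$params$k
  guilds <- config$params$states

  sims <- tick("simulate", simulate_tree_set(
    config$params, config$root_state, n_extant = config$n_extant,
    n_trees = config$n_trees, seed = derive_seed(config$seed, "treesim")))

  rates <- tick("dr", lapply(sims, function(s) dr_statistic(s$tree)))
  shared <- all(vapply(rates, function(r)
    setequal(names(r), names(rates[[1]])), TRUE))
  pooled <- if (shared && config$n_trees > 1) pool_median(rates) else NULL

  ## modelling table: per-tree rows stacked (independent trees do not
  ## share tips, so per-tip median pooling does not apply; see vignette)
  tabs <- tick("traits", lapply(seq_along(sims), function(i)
    trait_table_for_tree(sims[[i]], guilds,
                         derive_seed(config$seed, paste0("traits:", i)))))
  model_tab <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    d <- tabs[[i]]; d$tree <- i
    d$rate <- unname(rates[[i]][d$species])
    d
  }))
  if (!is.null(config$filter)) {
    keep <- config$filter(model_tab)
    model_tab <- model_tab[keep, , drop = FALSE]
  }
  model_tab <- model_tab[complete.cases(model_tab), , drop = FALSE]

  bspec <- do.call(boost_spec, c(config$boost,
                                 list(seed = derive_seed(config$seed, "boost"))))
  boost_res <- tick("boost", {
    tuned <- tune_two_step(model_tab, model_tab$rate, bspec)
    cv <- fit_and_validate(model_tab, model_tab$rate, tuned$best, bspec)
    models <- bootstrap_models(model_tab, model_tab$rate, tuned$best,
                               bspec$n_boot, bspec)
    imp <- bootstrap_importance(models = models)
    prof <- predict_profiles(models, model_tab)
    eff <- size_class_effects(prof)
    list(tuned = tuned, cv = cv, importance = imp, profiles = prof,
         effects = eff)
  })

  sse_res <- tick("sse", {
    fits <- lapply(seq_along(sims), function(i)
      musse_ml(sims[[i]]$tree, sims[[i]]$states, k = k))
    draws <- lapply(seq_along(sims), function(i)
      musse_mcmc(sims[[i]]$tree, sims[[i]]$states, start = fits[[i]],
                 n_gen = config$mcmc$n_gen,
                 n_prelim = config$mcmc$n_prelim,
                 burn_frac = config$mcmc$burn_frac,
                 seed = derive_seed(config$seed, paste0("mcmc:", i)),
                 tree_id = i))
    list(fits = fits, draws = draws,
         summary = pool_and_summarize(draws))
  })

  trans_res <- tick("charmap", {
    hists <- unlist(lapply(seq_along(sims), function(i) {
      asr <- marginal_asr(sims[[i]]$tree, sims[[i]]$states,
                          sse_res$fits[[i]]$params)
      sample_histories(params = sse_res$fits[[i]]$params, marginals = asr,
                       n_maps = config$n_maps,
                       seed = derive_seed(config$seed, paste0("simmap:", i)))
    }), recursive = FALSE)
    counts <- count_transitions(hists, k = k)
    list(counts = counts, chord = chord_table(counts, guilds),
         annotation = sprintf("averaged over %d trees x %d maps",
                              config$n_trees, config$n_maps))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("reefdiv")),
    seed = config$seed,
    config = config_echo(config),
    stage_seconds = lapply(stages, round, 2),
    total_seconds = round(proc.time()[3] - t_start, 2),
    transition_annotation = trans_res$annotation)

  if (!is.null(out_dir)) {
    for (i in seq_along(sims)) {
      write_newick(sims[[i]]$tree,
                   file.path(out_dir, sprintf("tree_%03d.nwk", i)))
      write_tip_states(sims[[i]]$states,
                       file.path(out_dir, sprintf("states_%03d.tsv", i)))
    }
    if (!is.null(pooled))
      write.table(pooled, file.path(out_dir, "tip_rates.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    write_trait_table(model_tab, file.path(out_dir, "model_table.tsv"))
    write.table(boost_res$importance, file.path(out_dir, "importance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(boost_res$effects, file.path(out_dir, "size_effects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_fit_json(sse_res$summary, file.path(out_dir, "sse_summary.json"))
    write_draws_tsv(sse_res$draws, file.path(out_dir, "draws.tsv"))
    write.table(trans_res$chord, file.path(out_dir, "transitions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$file_md5 <- as.list(tools::md5sum(files))
    names(manifest$file_md5) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(trees = sims, tip_rates = list(per_tree = rates, pooled = pooled),
       model_table = model_tab, boost = boost_res, sse = sse_res,
       transitions = trans_res, manifest = manifest)
}

## JSON-serialisable echo of the config (functions deparsed)
config_echo <- function(config) {
  list(seed = config$seed, n_trees = config$n_trees,
       n_extant = config$n_extant,
       lam = config$params$lam, mu = config$params$mu,
       Q = config$params$Q, guilds = config$params$states,
       root_state = config$root_state, mcmc = config$mcmc,
       n_maps = config$n_maps, boost = config$boost,
       filter = if (is.null(config$filter)) NULL else
         paste(deparse(config$filter), collapse = " "))
}
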