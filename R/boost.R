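#' Specification of the gradient-boosting protocol
#'
#' Bundles the hyperparameter search grids, cross-validation and
#' bootstrap settings of the tip-rate attribution stage. The model is a
#' gradient-boosted regression tree ensemble with a gamma deviance
#' objective (tip rates are strictly positive and right-skewed). Tuning
#' is two-step: a systematic sweep over `grid`, then `n_draws` random
#' refinements drawn uniformly within `jitter_frac` (default 10%) of the
#' stage-1 optimum.
#'
#' @param grid Named list of stage-1 values for `eta` (learning rate),
#'   `max_depth`, `gamma` (minimum split loss) and `subsample`.
#' @param n_draws Stage-2 random draws (protocol default 1000).
#' @param jitter_frac Stage-2 half-width as a fraction of the stage-1
#'   best (default 0.10).
#' @param n_boot Bootstrap refits for importance/prediction intervals
#'   (protocol default 1000).
#' @param cv_reps Cross-validation repetitions (protocol default 1000).
#' @param train_frac Training fraction of each split (default 0.8).
#' @param nrounds Boosting rounds per fit.
#' @param seed Master seed for tuning draws, splits and resamples.
#' @return A `boost_spec` list.
#' @export
boost_spec <- function(grid = list(eta = c(0.01, 0.05, 0.1, 0.3),
                                   max_depth = c(2, 4, 6, 8),
                                   gamma = c(0, 1, 5),
                                   subsample = c(0.5, 0.75, 1.0)),
                       n_draws = 1000, jitter_frac = 0.10, n_boot = 1000,
                       cv_reps = 1000, train_frac = 0.8, nrounds = 100,
                       seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, n_draws >= 1, n_boot >= 1,
            cv_reps >= 1, jitter_frac >= 0, jitter_frac < 1)
  if (!all(c("eta", "max_depth", "gamma", "subsample") %in% names(grid)))
    stop_reefdiv("grid must name eta, max_depth, gamma and subsample")
  if (!length(expand.grid(grid))) stop_reefdiv("empty tuning grid")
  structure(list(grid = grid, n_draws = n_draws, jitter_frac = jitter_frac,
                 n_boot = n_boot, cv_reps = cv_reps, train_frac = train_frac,
                 nrounds = nrounds, seed = as.integer(seed)),
            class = "boost_spec")
}

xgb_fit <- function(X, y, hp, nrounds, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y)
  params <- list(objective = "reg:gamma", eta = hp$eta,
                 max_depth = as.integer(round(hp$max_depth)),
                 gamma = hp$gamma, subsample = hp$subsample,
                 nthread = 1, seed = seed)
  xgboost::xgb.train(params = params, data = dm, nrounds = nrounds,
                     verbose = 0)
}

xgb_rmse <- function(model, X, y) {
  sqrt(mean((predict(model, xgboost::xgb.DMatrix(X)) - y)^2))
}

#' Two-step hyperparameter tuning
#'
#' Stage 1 fits every combination of the predefined grid and scores it
#' by root-mean-square error on a held-out validation fifth of the rows.
#' Stage 2 refits `n_draws` models with each parameter drawn uniformly
#' within ±`jitter_frac` of the stage-1 optimum (depth rounded back to
#' an integer) and returns the rmse-minimising draw; ties break to the
#' first encountered. All draws and the validation split derive from
#' `spec$seed`.
#'
#' @param table Feature table (see [assemble_features] or
#'   [simulate_trait_table]).
#' @param response Positive numeric response (median tip rates), length
#'   `nrow(table)`.
#' @param spec A [boost_spec].
#' @return List: `best` (named list of tuned hyperparameters),
#'   `stage1_best`, `stage1_rmse`, `stage2_rmse`, `stage2_draws`.
#' @export
tune_two_step <- function(table, response, spec = boost_spec()) {
  stopifnot(length(response) == nrow(table))
  if (any(response <= 0)) stop_reefdiv("gamma objective needs response > 0")
  enc <- encode_features(table)
  set.seed(derive_seed(spec$seed, "tune-split"))
  n <- nrow(table)
  idx <- sample.int(n, floor(spec$train_frac * n))
  Xtr <- enc$X[idx, , drop = FALSE]; ytr <- response[idx]
  Xva <- enc$X[-idx, , drop = FALSE]; yva <- response[-idx]

  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  rmse1 <- vapply(seq_len(nrow(combos)), function(i) {
    hp <- as.list(combos[i, ])
    m <- xgb_fit(Xtr, ytr, hp, spec$nrounds,
                 derive_seed(spec$seed, paste0("tune1:", i)))
    xgb_rmse(m, Xva, yva)
  }, 0)
  best1 <- as.list(combos[which.min(rmse1), ])

  set.seed(derive_seed(spec$seed, "tune-stage2"))
  draws <- lapply(seq_len(spec$n_draws), function(i) {
    hp <- lapply(best1, function(v)
      runif(1, v * (1 - spec$jitter_frac), v * (1 + spec$jitter_frac)))
    hp$max_depth <- max(1L, as.integer(round(hp$max_depth)))
    hp$subsample <- min(hp$subsample, 1)
    hp
  })
  rmse2 <- vapply(seq_along(draws), function(i) {
    m <- xgb_fit(Xtr, ytr, draws[[i]], spec$nrounds,
                 derive_seed(spec$seed, paste0("tune2:", i)))
    xgb_rmse(m, Xva, yva)
  }, 0)
  best2 <- draws[[which.min(rmse2)]]
  list(best = best2, stage1_best = best1, stage1_rmse = min(rmse1),
       stage2_rmse = min(rmse2), stage2_draws = draws)
}

#' Fit the final model and cross-validate accuracy and precision
#'
#' Repeats `cv_reps` random 80/20 train/test splits: the model is refit
#' on the training part and predicts the held-out fifth. Accuracy is the
#' signed average bias, mean(observed - predicted), reported raw and as
#' a percentage of the mean response; precision is the R-squared of a
#' linear model between measured and predicted rates. Splits in which
#' the test response or the predictions are constant are skipped and
#' counted. The final model is refit on all rows.
#'
#' @inheritParams tune_two_step
#' @param hp Tuned hyperparameters (from [tune_two_step]`$best`).
#' @return List: `model` (final xgboost handle), `encoder`, `accuracy`
#'   (mean bias), `accuracy_pct` (bias as % of mean response),
#'   `precision` (mean R-squared), `per_rep` (data frame of per-split
#'   bias and R-squared), `n_skipped`.
#' @export
fit_and_validate <- function(table, response, hp, spec = boost_spec()) {
  stopifnot(length(response) == nrow(table))
  if (any(response <= 0)) stop_reefdiv("gamma objective needs response > 0")
  enc <- encode_features(table)
  n <- nrow(table)
  bias <- r2 <- rep(NA_real_, spec$cv_reps)
  set.seed(derive_seed(spec$seed, "cv"))
  for (rep in seq_len(spec$cv_reps)) {
    idx <- sample.int(n, floor(spec$train_frac * n))
    ytest <- response[-idx]
    if (sd(ytest) == 0) next
    m <- xgb_fit(enc$X[idx, , drop = FALSE], response[idx], hp,
                 spec$nrounds, derive_seed(spec$seed, paste0("cv:", rep)))
    pred <- predict(m, xgboost::xgb.DMatrix(enc$X[-idx, , drop = FALSE]))
    if (sd(pred) == 0) next
    bias[rep] <- mean(ytest - pred)
    r2[rep] <- summary(lm(ytest ~ pred))$r.squared
  }
  ok <- !is.na(bias)
  if (!any(ok)) stop_reefdiv("all cross-validation splits degenerate")
  model <- xgb_fit(enc$X, response, hp, spec$nrounds,
                   derive_seed(spec$seed, "final"))
  list(model = model, encoder = enc,
       accuracy = mean(bias[ok]),
       accuracy_pct = 100 * mean(bias[ok]) / mean(response),
       precision = mean(r2[ok]),
       per_rep = data.frame(rep = which(ok), bias = bias[ok], r2 = r2[ok]),
       n_skipped = sum(!ok))
}

#' Bootstrap refits of the final model
#'
#' Resamples rows (species) with replacement `n_boot` times and refits
#' the tuned model on each resample. Species rows are treated as
#' exchangeable; phylogenetic non-independence is not corrected, which
#' mirrors the protocol this stage implements and is documented as a
#' caveat.
#'
#' @inheritParams fit_and_validate
#' @param n_boot Number of bootstrap refits.
#' @return List of xgboost models with the encoder and row indices as
#'   attributes.
#' @export
bootstrap_models <- function(table, response, hp, n_boot = 1000,
                             spec = boost_spec()) {
  enc <- encode_features(table)
  n <- nrow(table)
  set.seed(derive_seed(spec$seed, "boot"))
  idxs <- lapply(seq_len(n_boot), function(b) sample.int(n, n, replace = TRUE))
  models <- lapply(seq_len(n_boot), function(b) {
    xgb_fit(enc$X[idxs[[b]], , drop = FALSE], response[idxs[[b]]], hp,
            spec$nrounds, derive_seed(spec$seed, paste0("boot:", b)))
  })
  structure(models, encoder = enc, indices = idxs, class = "boost_models")
}

#' Bootstrapped relative variable importance
#'
#' For every bootstrap refit, gain-based importance of the encoded
#' columns is aggregated back to the source variables (one-hot dummies
#' sum into their parent categorical) and normalised to 100%. The
#' summary reports the mean and 25/75% quantiles across bootstraps,
#' together with the chance-expectation line 100/p % for p variables:
#' the importance a variable would get if all contributed equally.
#'
#' @inheritParams bootstrap_models
#' @param models Optionally, a precomputed [bootstrap_models] result.
#' @return Data frame `variable`, `mean`, `q25`, `q75`, sorted by mean
#'   descending; attributes `chance` (%) and `matrix` (per-bootstrap
#'   importance, variables x bootstraps).
#' @export
bootstrap_importance <- function(table = NULL, response = NULL, hp = NULL,
                                 n_boot = 1000, spec = boost_spec(),
                                 models = NULL) {
  models <- models %||% bootstrap_models(table, response, hp, n_boot, spec)
  enc <- attr(models, "encoder")
  vars <- enc$predictors
  imp <- vapply(models, function(m) {
    it <- xgboost::xgb.importance(model = m)
    per_col <- setNames(it$Gain, it$Feature)
    v <- vapply(vars, function(g) {
      sum(per_col[names(enc$groups)[enc$groups == g]], na.rm = TRUE)
    }, 0)
    100 * v / sum(v)
  }, numeric(length(vars)))
  out <- data.frame(variable = vars,
                    mean = rowMeans(imp),
                    q25 = apply(imp, 1, quantile, 0.25),
                    q75 = apply(imp, 1, quantile, 0.75),
                    row.names = NULL)
  out <- out[order(-out$mean), ]
  structure(out, chance = 100 / length(vars), matrix = imp)
}

## held-at values: continuous at the mean, categoricals at the mode
held_values <- function(table, vary) {
  held <- list()
  for (v in PREDICTORS) {
    if (v %in% vary) next
    x <- table[[v]]
    if (v %in% CATEGORICAL || is.factor(x) || is.character(x)) {
      tab <- table(x)
      held[[v]] <- names(tab)[which.max(tab)]
    } else {
      held[[v]] <- mean(x)
    }
  }
  held
}

#' Bootstrap prediction profiles over trophic guild (and body size)
#'
#' Predicts tip rates on a grid over the varied predictors — all guild
#' levels, and optionally a body-size grid spanning the observed range —
#' while every other continuous variable is held at its mean and every
#' other categorical at its most common level. Each bootstrap model
#' predicts the whole grid; the summary keeps the median and 25/75%
#' quantiles per grid point.
#'
#' @param models A [bootstrap_models] result.
#' @param table The modelling table the held-at values are computed from.
#' @param vary `"trophic"` or `c("trophic", "size")`.
#' @param size_grid_n Number of size-grid points (default 25).
#' @return Data frame with the grid columns and `median`, `q25`, `q75`
#'   (per-model prediction matrix in attribute `"matrix"`). Grid values
#'   outside the observed training range are flagged via attribute
#'   `"extrapolated"`.
#' @export
predict_profiles <- function(models, table, vary = c("trophic", "size"),
                             size_grid_n = 25) {
  stopifnot(inherits(models, "boost_models"))
  vary <- match.arg(vary, c("trophic", "size"), several.ok = TRUE)
  enc <- attr(models, "encoder")
  held <- held_values(table, vary)
  guilds <- levels(factor(table$trophic))
  grid <- if ("size" %in% vary) {
    sz <- seq(min(table$size), max(table$size), length.out = size_grid_n)
    expand.grid(trophic = guilds, size = sz, KEEP.OUT.ATTRS = FALSE,
                stringsAsFactors = FALSE)
  } else {
    data.frame(trophic = guilds, stringsAsFactors = FALSE)
  }
  newdat <- grid
  for (v in names(held)) newdat[[v]] <- held[[v]]
  for (v in CATEGORICAL)
    newdat[[v]] <- factor(newdat[[v]], levels = levels(factor(table[[v]])))
  Xg <- encode_features(newdat)$X[, colnames(enc$X), drop = FALSE]
  dm <- xgboost::xgb.DMatrix(Xg)
  preds <- vapply(models, function(m) predict(m, dm), numeric(nrow(Xg)))
  preds <- matrix(preds, nrow = nrow(Xg))
  out <- cbind(grid,
               median = apply(preds, 1, median),
               q25 = apply(preds, 1, quantile, 0.25),
               q75 = apply(preds, 1, quantile, 0.75))
  structure(out, matrix = preds, held = held,
            extrapolated = if ("size" %in% vary) logical(nrow(grid)) else NULL)
}

#' Per-size-class trophic effect sizes
#'
#' Splits the size grid of a trophic-by-size profile into classes at the
#' given breaks (default < 10 cm, 10-30 cm, > 30 cm) and, within each
#' class and bootstrap model, computes each guild's effect as its median
#' predicted rate minus the global median predicted rate in that class.
#' Bootstrap variability is propagated: the summary reports the median
#' and 25/75% quantiles of the per-model effects. Effects across guilds
#' need not sum to zero (medians, not means).
#'
#' @param profiles A trophic-by-size profile from [predict_profiles].
#' @param breaks Size-class boundaries in cm (default `c(10, 30)`).
#' @return Data frame `class`, `trophic`, `median`, `q25`, `q75`.
#' @export
size_class_effects <- function(profiles, breaks = c(10, 30)) {
  if (!"size" %in% names(profiles))
    stop_reefdiv("profiles must vary trophic and size")
  preds <- attr(profiles, "matrix")
  cls <- cut(profiles$size, c(-Inf, breaks, Inf),
             labels = c(sprintf("<%g", breaks[1]),
                        sprintf("%g-%g", breaks[1], breaks[2]),
                        sprintf(">%g", breaks[2])))
  if (any(table(cls) == 0))
    stop_reefdiv("a size class contains no grid points; widen the grid")
  guilds <- unique(profiles$trophic)
  rows <- list()
  for (cl in levels(cls)) {
    in_cl <- cls == cl
    global_med <- apply(preds[in_cl, , drop = FALSE], 2, median)
    for (g in guilds) {
      sel <- in_cl & profiles$trophic == g
      eff <- apply(preds[sel, , drop = FALSE], 2, median) - global_med
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, trophic = g, median = median(eff),
        q25 = quantile(eff, 0.25), q75 = quantile(eff, 0.75),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
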