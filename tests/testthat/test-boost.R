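## small shared settings: reduced bootstrap/CV counts keep the suite quick
## while leaving the protocol structure intact
quick_spec <- function(...) {
  args <- modifyList(
    list(grid = list(eta = c(0.05, 0.1), max_depth = c(3, 5), gamma = 0,
                     subsample = 1),
         n_draws = 10, n_boot = 20, cv_reps = 20, nrounds = 60, seed = 7),
    list(...))
  do.call(boost_spec, args)
}

planted_table <- function(n = 1200, ratio = 2, noise_shape = 8, seed = 42) {
  simulate_trait_table(trait_gen_spec(
    n, rate_fn = function(g, s) ifelse(g == "HD", 0.1 * ratio, 0.1),
    noise_shape = noise_shape, seed = seed))
}

test_that("feature assembly computes ranges, centroids and IAA distances", {
  occ <- data.frame(
    species = c("sp1", "sp2", "sp2", "sp3", "sp3"),
    lat = c(0, 10, -10, 0, 0),
    lon = c(121, 121, 121, 122, 122))
  traits <- data.frame(
    species = c("sp1", "sp2", "sp3", "sp4"),
    trophic = factor(c("HD", "GC", "OM", "PK")),
    size = c(10, 20, 30, 40),
    activity = factor(rep("diurnal", 4)),
    position = factor(rep("benthic", 4)),
    basin = factor(rep("Indo-Pacific", 4)),
    sst = rep(27, 4), prprod = rep(500, 4))
  expect_message(ft <- assemble_features(occ, traits), "dropping 1 species")
  expect_equal(attr(ft, "dropped"), "sp4")
  ## sp1 sits exactly on the reference point
  expect_equal(ft$range[ft$species == "sp1"], 1)
  expect_equal(ft$dist_iaa[ft$species == "sp1"], 0)
  expect_equal(ft$abs_lat[ft$species == "sp1"], 0)
  ## symmetric cells: centroid on the equator
  expect_equal(ft$range[ft$species == "sp2"], 2)
  expect_equal(ft$abs_lat[ft$species == "sp2"], 0)
  expect_equal(ft$dist_iaa[ft$species == "sp2"], 0, tolerance = 1e-6)
  ## one degree of longitude at the equator = pi/180 * 6371 km
  expect_equal(ft$dist_iaa[ft$species == "sp3"], pi / 180 * 6371,
               tolerance = 1e-3)
  bad <- occ; bad$lat[1] <- 95
  expect_error(assemble_features(bad, traits), "out of range")
})

test_that("two-step tuning honours its contracts", {
  tt <- planted_table(400)
  ## single combination, zero jitter: returned unchanged
  sp1 <- boost_spec(grid = list(eta = 0.1, max_depth = 4, gamma = 0,
                                subsample = 1),
                    n_draws = 5, jitter_frac = 0, nrounds = 30, seed = 3)
  tuned1 <- tune_two_step(tt$table, tt$true_rates, sp1)
  expect_equal(tuned1$best,
               list(eta = 0.1, max_depth = 4L, gamma = 0, subsample = 1))

  ## every stage-2 draw within +/-10% of the stage-1 best
  sp2 <- quick_spec()
  tuned2 <- tune_two_step(tt$table, tt$true_rates, sp2)
  b1 <- tuned2$stage1_best
  for (d in tuned2$stage2_draws) {
    expect_gte(d$eta, b1$eta * 0.9 - 1e-12)
    expect_lte(d$eta, b1$eta * 1.1 + 1e-12)
    expect_gte(d$subsample, b1$subsample * 0.9 - 1e-12)
    expect_lte(d$gamma, b1$gamma * 1.1 + 1e-12)
    expect_gte(d$max_depth, 1)
  }
  ## stage 2 searches a neighbourhood of the stage-1 optimum
  expect_lte(tuned2$stage2_rmse, tuned2$stage1_rmse * 1.05)
  expect_error(tune_two_step(tt$table, -tt$true_rates, sp2), "response > 0")
  expect_error(boost_spec(grid = list(eta = 0.1)), "grid must name")
})

test_that("cross-validation recovers noiseless signal and rejects none", {
  ## response an exact function of one feature: R^2 -> 1, bias -> 0
  spc <- trait_gen_spec(800, rate_fn = function(g, s) 0.05 + 0.002 * s,
                        noise_shape = 1e9, seed = 11)
  tt <- simulate_trait_table(spc)
  hp <- list(eta = 0.1, max_depth = 4, gamma = 0, subsample = 1)
  cv <- fit_and_validate(tt$table, tt$true_rates, hp,
                         quick_spec(cv_reps = 30, seed = 5))
  expect_gt(cv$precision, 0.95)
  expect_lt(abs(cv$accuracy) / mean(tt$true_rates), 0.05)

  ## pure gamma noise, no signal: mean R^2 near zero
  spc0 <- trait_gen_spec(800, rate_fn = function(g, s) rep(0.1, length(g)),
                         noise_shape = 4, seed = 12)
  tt0 <- simulate_trait_table(spc0)
  cv0 <- fit_and_validate(tt0$table, tt0$true_rates, hp,
                          quick_spec(cv_reps = 40, seed = 6))
  expect_gt(cv0$precision, -0.05)
  expect_lt(cv0$precision, 0.1)
})

test_that("overfit sanity: deep unregularised fits interpolate training rows", {
  tt <- planted_table(300)
  hp <- list(eta = 0.5, max_depth = 10, gamma = 0, subsample = 1)
  enc <- reefdiv:::encode_features(tt$table)
  m <- reefdiv:::xgb_fit(enc$X, tt$true_rates, hp, nrounds = 400, seed = 1)
  pred <- predict(m, xgboost::xgb.DMatrix(enc$X))
  expect_gt(cor(pred, tt$true_rates)^2, 0.98)
})

test_that("bootstrap importance finds the planted predictor and normalises", {
  tt <- planted_table(1200)
  hp <- list(eta = 0.1, max_depth = 4, gamma = 0, subsample = 1)
  models <- bootstrap_models(tt$table, tt$true_rates, hp, n_boot = 30,
                             spec = quick_spec())
  imp <- bootstrap_importance(models = models)
  expect_equal(attr(imp, "chance"), 10)  # p = 10 predictors
  expect_equal(imp$variable[1], "trophic")
  m <- attr(imp, "matrix")
  ## normalisation to 100% per bootstrap
  expect_true(all(abs(colSums(m) - 100) < 1e-6))
  ## the planted predictor tops every bootstrap and beats chance
  expect_true(all(m["trophic", ] > 10))
  expect_true(all(m["trophic", ] == apply(m, 2, max)))
})

test_that("permuting a predictor collapses its importance toward chance", {
  tt <- planted_table(800)
  hp <- list(eta = 0.1, max_depth = 4, gamma = 0, subsample = 1)
  imp0 <- bootstrap_importance(tt$table, tt$true_rates, hp, n_boot = 10,
                               spec = quick_spec(seed = 8))
  tab_perm <- tt$table
  set.seed(99)
  tab_perm$trophic <- sample(tab_perm$trophic)
  imp1 <- bootstrap_importance(tab_perm, tt$true_rates, hp, n_boot = 10,
                               spec = quick_spec(seed = 8))
  tr0 <- imp0$mean[imp0$variable == "trophic"]
  tr1 <- imp1$mean[imp1$variable == "trophic"]
  expect_lt(tr1, tr0 / 2)
  expect_lt(tr1, 2 * attr(imp1, "chance"))
})

test_that("profiles hold covariates fixed and expose planted contrasts", {
  tt <- planted_table(1200)
  hp <- list(eta = 0.1, max_depth = 4, gamma = 0, subsample = 1)
  models <- bootstrap_models(tt$table, tt$true_rates, hp, n_boot = 25,
                             spec = quick_spec())
  prof <- predict_profiles(models, tt$table)
  expect_true(all(c("trophic", "size", "median", "q25", "q75") %in%
                  names(prof)))
  expect_true(all(prof$q25 <= prof$median + 1e-12 &
                  prof$median <= prof$q75 + 1e-12))
  ## HD = 2x GC planted at all sizes: HD median above GC at >= 95% of
  ## the size grid
  hd <- prof[prof$trophic == "HD", ]
  gc <- prof[prof$trophic == "GC", ]
  expect_gte(mean(hd$median > gc$median), 0.95)

  ## trophic-only profile on a constant response: flat medians
  spc <- trait_gen_spec(300, rate_fn = function(g, s) rep(0.1, length(g)),
                        noise_shape = 1e9, seed = 13)
  tt0 <- simulate_trait_table(spc)
  m0 <- bootstrap_models(tt0$table, tt0$true_rates, hp, n_boot = 5,
                         spec = quick_spec())
  p0 <- predict_profiles(m0, tt0$table, vary = "trophic")
  expect_lt(diff(range(p0$median)), 0.01 * 0.1 + 1e-3)
})

test_that("size-class effects isolate the planted guild at every size", {
  tt <- planted_table(1200)
  hp <- list(eta = 0.1, max_depth = 4, gamma = 0, subsample = 1)
  models <- bootstrap_models(tt$table, tt$true_rates, hp, n_boot = 25,
                             spec = quick_spec())
  prof <- predict_profiles(models, tt$table)
  eff <- size_class_effects(prof)
  expect_equal(sort(unique(as.character(eff$class))),
               sort(c("<10", "10-30", ">30")))
  hd <- eff[eff$trophic == "HD", ]
  expect_true(all(hd$median > 0))       # positive in every size class
  for (cl in unique(eff$class)) {
    sub <- eff[eff$class == cl, ]
    expect_equal(sub$trophic[which.max(sub$median)], "HD")
  }
  expect_error(size_class_effects(predict_profiles(models, tt$table,
                                                   vary = "trophic")),
               "vary trophic and size")
})
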