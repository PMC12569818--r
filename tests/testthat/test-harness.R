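test_that("the oracle regressor yields perfect metrics on noiseless data", {
  sim <- small_sim(seed = 8, noise_sd = 0)
  res <- run_ddg_experiment(sim, model = "oracle", strategy = "random",
                            n_repeats = 3, base_seed = 1)
  expect_identical(nrow(res), 3L)
  expect_false(any(res$failed))
  expect_equal(res$pearson, rep(1, 3), tolerance = 1e-10)
  expect_equal(res$mae, rep(0, 3), tolerance = 1e-10)
  s <- summarize_benchmark(res)
  expect_equal(s$mean[s$metric == "pearson"], 1, tolerance = 1e-10)
  expect_equal(s$sd[s$metric == "pearson"], 0, tolerance = 1e-10)
})

test_that("oracle pairwise recovery is exact at zero noise", {
  sim <- small_sim(seed = 8, noise_sd = 0, n_groups = 17,
                   records_per_group = 10)
  res <- run_ddg_experiment(sim, model = "oracle", strategy = "uniprot",
                            paired = TRUE, anchor_ratio = 0.3,
                            n_repeats = 2, base_seed = 1)
  expect_false(any(res$failed))
  expect_equal(res$pearson, rep(1, 2), tolerance = 1e-10)
})

test_that("repeats with forced identical seeds have zero spread", {
  sim <- small_sim(seed = 8)
  r1 <- run_ddg_experiment(sim, model = "rf", n_repeats = 1, base_seed = 5,
                           hyperparams = list(num.trees = 50))
  r2 <- run_ddg_experiment(sim, model = "rf", n_repeats = 1, base_seed = 5,
                           hyperparams = list(num.trees = 50))
  both <- dplyr::bind_rows(r1, r2)
  s <- summarize_benchmark(both)
  expect_equal(s$sd, rep(0, nrow(s)), tolerance = 1e-12)
  # seeds are logged per repeat
  expect_identical(both$seed, c(5L, 5L))
})

test_that("failed repeats are recorded, not raised", {
  sim <- small_sim(seed = 8, n_groups = 3, records_per_group = 4)
  # 3 groups cannot be uniprot-partitioned with val_first: every repeat fails
  res <- run_ddg_experiment(sim, model = "rf", strategy = "uniprot",
                            n_repeats = 2, base_seed = 1)
  expect_true(all(res$failed))
  expect_true(all(grepl("groups", res$error)))
  s <- summarize_benchmark(res)
  expect_identical(unique(s$n_failed), 2L)
})

test_that("random vs grouped splitting opens a performance gap", {
  # scaled-down shift benchmark: the gap direction is the property; the
  # full-scale magnitudes are exercised by the acceptance suite
  sim <- small_sim(seed = 30, n_groups = 10, records_per_group = 15,
                   embedding_dim = 128)
  hp <- list(num.trees = 200)
  r_rand <- run_ddg_experiment(sim, model = "rf", strategy = "random",
                               n_repeats = 3, base_seed = 1, hyperparams = hp)
  r_uni <- run_ddg_experiment(sim, model = "rf", strategy = "uniprot",
                              n_repeats = 3, base_seed = 1, hyperparams = hp)
  expect_false(any(r_rand$failed) || any(r_uni$failed))
  expect_gt(mean(r_rand$pearson), mean(r_uni$pearson) + 0.2)
  expect_gt(mean(r_rand$pearson), 0.7)
})

test_that("anchor-query pairing rescues grouped-split prediction", {
  sim <- small_sim(seed = 31, n_groups = 18, records_per_group = 20,
                   embedding_dim = 64)
  hp <- list(num.trees = 200)
  base <- run_ddg_experiment(sim, model = "rf", strategy = "uniprot",
                             n_repeats = 3, base_seed = 2, hyperparams = hp)
  paired <- run_ddg_experiment(sim, model = "rf", strategy = "uniprot",
                               paired = TRUE, anchor_ratio = 0.3,
                               n_repeats = 3, base_seed = 2, hyperparams = hp,
                               max_pairs_per_group = 60)
  expect_false(any(paired$failed))
  expect_gt(mean(paired$pearson), mean(base$pearson) + 0.3)
  expect_gt(mean(paired$pearson), 0.6)
  # queries without a same-group anchor are counted, never silently dropped
  expect_true(all(paired$n_uncovered >= 0))
  expect_true(all(paired$n_eval + paired$n_uncovered >= paired$n_eval))
})

test_that("prediction quality is non-decreasing in the anchor ratio", {
  sim <- small_sim(seed = 32, n_groups = 18, records_per_group = 20,
                   embedding_dim = 64)
  res <- compare_anchor_strategies(sim, ratios = c(0, 0.3, 0.6, 0.9),
                                   model = "rf",
                                   hyperparams = list(num.trees = 200),
                                   n_repeats = 5, base_seed = 1,
                                   max_pairs_per_group = 60)
  s <- summarize_benchmark(res)
  # gradual introduction of reference data into the training set: mean
  # query Pearson rises monotonically with the anchor ratio
  unpaired <- s[s$metric == "pearson" & !s$paired, ]
  unpaired <- unpaired[order(unpaired$anchor_ratio), ]
  expect_identical(nrow(unpaired), 4L)
  expect_true(all(diff(unpaired$mean) > -0.05))  # non-decreasing up to noise
  # and pairing beats the unpaired baseline at the matched ratio
  paired <- s[s$metric == "pearson" & s$paired, ]
  expect_gt(paired$mean[paired$anchor_ratio == 0.3],
            unpaired$mean[unpaired$anchor_ratio == 0.3])
})

test_that("whole runs are reproducible from their seeds", {
  sim <- small_sim(seed = 33, n_groups = 6, records_per_group = 8)
  hp <- list(num.trees = 100)
  a <- run_ddg_experiment(sim, model = "rf", n_repeats = 2, base_seed = 4,
                          hyperparams = hp)
  b <- run_ddg_experiment(sim, model = "rf", n_repeats = 2, base_seed = 4,
                          hyperparams = hp)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("pair-weight recovery estimates the generator weights", {
  sim <- small_sim(seed = 34, n_groups = 8, records_per_group = 15,
                   embedding_dim = 64, noise_sd = 0.1)
  pairs <- build_training_pairs(sim$data, max_pairs_per_group = 60, seed = 1)
  w_hat <- recover_pair_weights(pairs, method = "lasso", seed = 1)
  w <- sim$truth$weights
  cosine <- sum(w_hat * w) / sqrt(sum(w_hat^2) * sum(w^2))
  expect_gt(cosine, 0.9)
})
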