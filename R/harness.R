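# Repeat harness: featurize -> split -> [pair] -> train -> predict -> metrics.

as_experiment_data <- function(x) {
  if (inherits(x, "ddg_simulation")) {
    list(data = x$data, truth = x$truth)
  } else if (is.data.frame(x)) {
    if (!"feature" %in% names(x)) {
      stop_ddg("`x` must be featurized; run featurize_mutation_data() first.")
    }
    list(data = x, truth = NULL)
  } else {
    stop_ddg("`x` must be a ddg_simulation or a featurized tibble.")
  }
}

#' Run a repeated ddG prediction experiment
#'
#' Executes the full evaluation pipeline `split -> [anchor selection ->
#' pairing] -> train -> predict -> metrics` for `n_repeats` independent
#' repeats with seeds `base_seed + 0, 1, ...`, and returns one tidy row of
#' test metrics per repeat. This is the workhorse behind all benchmark
#' comparisons: partitioning strategies, anchor ratios, and paired versus
#' unpaired use of reference data.
#'
#' Conditions:
#' * `paired = FALSE, anchor_ratio = 0` — plain: train on the training
#'   subset, evaluate on the full test subset.
#' * `paired = FALSE, anchor_ratio > 0` — unpaired reference baseline: the
#'   anchor records are moved into the training set and the model predicts
#'   the remaining queries directly.
#' * `paired = TRUE, anchor_ratio > 0` — anchor-query pairing: a pairwise
#'   model is trained on within-group training pairs (targets dddG), each
#'   query is paired with its same-group anchors, and per-query ddG is
#'   recovered as the ensemble mean of `pred_dddg + anchor_ddg`.
#'   Queries without a same-group anchor are skipped and counted.
#'
#' `model = "oracle"` (available when `x` is a simulation) predicts with
#' the generator's noise-free ground truth and is used to validate the
#' harness itself.
#'
#' @param x A `ddg_simulation` or a featurized mutation tibble.
#' @param model Registry name (see [register_regressor()]) or `"oracle"`.
#' @param strategy `"random"` or `"uniprot"` partitioning.
#' @param paired Use anchor-query pairing (requires `anchor_ratio > 0`).
#' @param anchor_ratio Fraction of the test set used as anchors, in
#'   `[0, 0.9]`.
#' @param hyperparams Named list forwarded to [fit_ddg_model()].
#' @param n_repeats Number of independent repeats (default 10).
#' @param base_seed First seed; repeat i uses `base_seed + i - 1` for the
#'   split, the anchor draw, the pair subsample and model training.
#' @param max_pairs_per_group Cap on training pairs per group in paired
#'   mode (default 100; keeps one repeat at desk scale).
#' @param pair_feature Pair feature construction, see [build_pairs()].
#' @return A tibble of class `ddg_benchmark`: one row per repeat with the
#'   condition columns, `seed`, `n_eval`, `n_uncovered`, the four metrics,
#'   and `failed`/`error` for repeats that raised. Summarise with
#'   [summarize_benchmark()], plot with [autoplot()].
#' @export
run_ddg_experiment <- function(x, model = "rf",
                               strategy = c("random", "uniprot"),
                               paired = FALSE, anchor_ratio = 0,
                               hyperparams = list(),
                               n_repeats = 10L, base_seed = 1L,
                               max_pairs_per_group = 100L,
                               pair_feature = c("difference", "concatenation")) {
  strategy <- match.arg(strategy)
  pair_feature <- match.arg(pair_feature)
  if (n_repeats < 1L) stop_ddg("`n_repeats` must be >= 1.")
  if (paired && anchor_ratio == 0) {
    warn("paired = TRUE with anchor_ratio = 0 falls back to plain prediction.")
  }
  xd <- as_experiment_data(x)
  rows <- lapply(seq_len(n_repeats), function(i) {
    seed <- as.integer(base_seed) + i - 1L
    res <- tryCatch(
      one_repeat(xd$data, xd$truth, model, strategy, paired, anchor_ratio,
                 hyperparams, seed, max_pairs_per_group, pair_feature),
      error = function(e) {
        list(n_eval = NA_integer_, n_uncovered = NA_integer_,
             mae = NA_real_, rmse = NA_real_, pearson = NA_real_,
             spearman = NA_real_, failed = TRUE,
             error = conditionMessage(e))
      }
    )
    tibble(
      rep = i, seed = seed, model = model, strategy = strategy,
      paired = paired, anchor_ratio = anchor_ratio,
      n_eval = res$n_eval, n_uncovered = res$n_uncovered,
      mae = res$mae, rmse = res$rmse,
      pearson = res$pearson, spearman = res$spearman,
      failed = res$failed %||% FALSE,
      error = res$error %||% NA_character_
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("ddg_benchmark", class(out))
  attr(out, "config") <- list(model = model, strategy = strategy,
                              paired = paired, anchor_ratio = anchor_ratio,
                              n_repeats = n_repeats, base_seed = base_seed,
                              max_pairs_per_group = max_pairs_per_group,
                              pair_feature = pair_feature)
  out
}

one_repeat <- function(data, truth, model, strategy, paired, anchor_ratio,
                       hyperparams, seed, max_pairs_per_group, pair_feature) {
  split_data <- if (strategy == "random") {
    partition_random(data, seed = seed)
  } else {
    partition_by_uniprot(data, seed = seed)
  }
  use_oracle <- identical(model, "oracle")
  if (use_oracle && is.null(truth)) {
    stop_ddg("model = \"oracle\" requires a ddg_simulation input.")
  }
  predict_records <- function(train_tbl, eval_tbl) {
    if (use_oracle) return(oracle_predict(truth, eval_tbl))
    fit <- fit_ddg_model(train_tbl, target = "ddg", model = model,
                         hyperparams = hyperparams, seed = seed)
    predict(fit, eval_tbl)
  }

  if (!paired || anchor_ratio == 0) {
    if (anchor_ratio > 0) {
      split_data <- select_anchors(split_data, ratio = anchor_ratio, seed = seed)
      train_tbl <- split_data[split_data$subset == "train" |
                                (!is.na(split_data$role) &
                                   split_data$role == "anchor"), ]
      eval_tbl <- split_data[!is.na(split_data$role) &
                               split_data$role == "query", ]
    } else {
      train_tbl <- split_data[split_data$subset == "train", ]
      eval_tbl <- split_data[split_data$subset == "test", ]
    }
    if (nrow(eval_tbl) < 2L) stop_ddg("evaluation subset too small.")
    pred <- predict_records(train_tbl, eval_tbl)
    m <- metrics_vec(eval_tbl$ddg, pred)
    return(c(list(n_eval = nrow(eval_tbl), n_uncovered = 0L,
                  failed = FALSE, error = NA_character_), m))
  }

  # anchor-query pairing
  split_data <- select_anchors(split_data, ratio = anchor_ratio, seed = seed)
  train_tbl <- split_data[split_data$subset == "train", ]
  train_pairs <- build_training_pairs(
    train_tbl, within_group_only = TRUE,
    max_pairs_per_group = max_pairs_per_group, seed = seed,
    pair_feature = pair_feature
  )
  if (!nrow(train_pairs)) stop_ddg("no training pairs could be formed.")
  test_pairs <- build_pairs(split_data, same_group_only = TRUE,
                            pair_feature = pair_feature)
  uncovered <- attr(test_pairs, "uncovered")
  if (!nrow(test_pairs)) stop_ddg("no query-anchor pairs could be formed.")

  pred_dddg <- if (use_oracle) {
    q_idx <- match(test_pairs$query_id, split_data$record_id)
    a_idx <- match(test_pairs$anchor_id, split_data$record_id)
    oracle_all <- oracle_predict(truth, split_data)
    oracle_all[q_idx] - oracle_all[a_idx]
  } else {
    fit <- fit_ddg_model(train_pairs, target = "target_dddg", model = model,
                         hyperparams = hyperparams, seed = seed)
    predict(fit, test_pairs)
  }
  test_pairs$pred_dddg <- pred_dddg
  recovered <- recover_query_ddg(test_pairs)
  truth_ddg <- split_data$ddg[match(recovered$query_id, split_data$record_id)]
  if (nrow(recovered) < 2L) stop_ddg("fewer than 2 covered queries.")
  m <- metrics_vec(truth_ddg, recovered$ddg_pred)
  c(list(n_eval = nrow(recovered), n_uncovered = length(uncovered),
         failed = FALSE, error = NA_character_), m)
}

#' Summarise a benchmark over repeats
#'
#' Aggregates per-repeat metrics to mean and standard deviation per
#' experimental condition, the mean +/- SD convention for repeated
#' evaluations. Failed repeats are excluded from the aggregation and
#' counted.
#'
#' @param results A `ddg_benchmark` tibble (rows from one or several
#'   [run_ddg_experiment()] calls bound together).
#' @return A tibble in long form: condition columns, `metric`, `mean`,
#'   `sd`, `n_repeats`, `n_failed`.
#' @export
summarize_benchmark <- function(results) {
  cond <- c("model", "strategy", "paired", "anchor_ratio")
  long <- tidyr::pivot_longer(
    as_tibble(results)[, c(cond, "failed", "mae", "rmse", "pearson", "spearman")],
    cols = c("mae", "rmse", "pearson", "spearman"),
    names_to = "metric", values_to = "value"
  )
  long |>
    group_by(across(all_of(c(cond, "metric")))) |>
    summarise(
      mean = mean(.data$value[!.data$failed]),
      sd = sd(.data$value[!.data$failed]),
      n_repeats = sum(!.data$failed),
      n_failed = sum(.data$failed),
      .groups = "drop"
    )
}

#' Compare paired and unpaired use of reference data across anchor ratios
#'
#' For each ratio, runs the unpaired baseline (anchors merged into the
#' training set) and the anchor-query paired pipeline under UniProt
#' partitioning, reproducing the reference-data sweep central to the
#' anchor-query analysis. A ratio of 0 is run once as the plain grouped
#' baseline (no reference data; identical for both arms).
#'
#' @inheritParams run_ddg_experiment
#' @param ratios Anchor ratios to sweep (default `c(0, 0.3, 0.6, 0.9)`).
#' @return A `ddg_benchmark` tibble covering all conditions; plot with
#'   [plot_anchor_curve()].
#' @export
compare_anchor_strategies <- function(x, ratios = c(0, 0.3, 0.6, 0.9),
                                      model = "rf", hyperparams = list(),
                                      n_repeats = 10L, base_seed = 1L,
                                      max_pairs_per_group = 100L) {
  out <- list()
  for (r in sort(unique(ratios))) {
    arms <- if (r == 0) list(FALSE) else list(FALSE, TRUE)
    for (p in arms) {
      out[[length(out) + 1L]] <- run_ddg_experiment(
        x, model = model, strategy = "uniprot", paired = p, anchor_ratio = r,
        hyperparams = hyperparams, n_repeats = n_repeats,
        base_seed = base_seed, max_pairs_per_group = max_pairs_per_group
      )
    }
  }
  res <- bind_rows(out)
  class(res) <- c("ddg_benchmark", class(res))
  res
}

#' Hyperparameter grid sweep
#'
#' Evaluates a list of model specifications on the validation subset over
#' repeated splits and selects the best one by highest mean validation
#' Pearson correlation, ties broken by lower RMSE.
#'
#' @inheritParams run_ddg_experiment
#' @param specs List of specifications, each a list with `model` and
#'   optionally `hyperparams`.
#' @return A tibble with one row per spec (`spec_id`, `model`,
#'   `hyperparams` list column, `mean_pearson`, `sd_pearson`, `mean_rmse`,
#'   `selected`); attribute `selected` holds the winning spec index.
#' @export
grid_sweep <- function(x, specs, strategy = c("random", "uniprot"),
                       n_repeats = 3L, base_seed = 1L) {
  strategy <- match.arg(strategy)
  if (!length(specs)) stop_ddg("`specs` must contain at least one specification.")
  xd <- as_experiment_data(x)
  rows <- imap(specs, function(spec, i) {
    vals <- vapply(seq_len(n_repeats), function(j) {
      seed <- as.integer(base_seed) + j - 1L
      sd_ <- if (strategy == "random") {
        partition_random(xd$data, seed = seed)
      } else {
        partition_by_uniprot(xd$data, seed = seed)
      }
      train_tbl <- sd_[sd_$subset == "train", ]
      val_tbl <- sd_[sd_$subset == "val", ]
      fit <- fit_ddg_model(train_tbl, target = "ddg", model = spec$model,
                           hyperparams = spec$hyperparams %||% list(),
                           seed = seed)
      pred <- predict(fit, val_tbl)
      m <- metrics_vec(val_tbl$ddg, pred)
      c(m$pearson, m$rmse)
    }, numeric(2))
    tibble(
      spec_id = i, model = spec$model,
      hyperparams = list(spec$hyperparams %||% list()),
      mean_pearson = mean(vals[1, ]), sd_pearson = sd(vals[1, ]),
      mean_rmse = mean(vals[2, ])
    )
  })
  out <- bind_rows(rows)
  ord <- order(-out$mean_pearson, out$mean_rmse)
  out$selected <- seq_len(nrow(out)) == ord[1]
  attr(out, "selected") <- ord[1]
  out
}

#' Recover generator weights from training pairs
#'
#' Fits a sparse (lasso) or ridge linear model of the pairwise dddG target
#' on the pair features. Because within-group pairing cancels every
#' group-constant contribution (offsets, and any feature constant within a
#' group), the estimate targets the identifiable component of the
#' label-generating weights; with the generator's sparse protein-block
#' signal this is the weight vector itself.
#'
#' @param pairs A training-pair tibble from [build_training_pairs()].
#' @param method `"lasso"` (default) or `"ridge"`.
#' @param seed Seed for the cross-validation folds.
#' @param nfolds Folds for `cv.glmnet` (default 5).
#' @return Numeric coefficient vector (no intercept), one entry per
#'   feature; attribute `lambda` records the selected penalty.
#' @export
recover_pair_weights <- function(pairs, method = c("lasso", "ridge"),
                                 seed = 1L, nfolds = 5L) {
  method <- match.arg(method)
  X <- feature_matrix(pairs, "pair_feature")
  y <- pairs$target_dddg
  if (any(!is.finite(y))) stop_ddg("pair targets must be finite.")
  cv <- with_local_seed(seed, {
    glmnet::cv.glmnet(X, y, alpha = if (method == "lasso") 1 else 0,
                      nfolds = nfolds)
  })
  w <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  attr(w, "lambda") <- cv$lambda.min
  w
}
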