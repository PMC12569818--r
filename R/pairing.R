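#' Build query-anchor pairs
#'
#' Pairs every query record with its eligible anchors and computes the pair
#' feature and (when labels are available) the pairwise regression target
#' \eqn{\Delta\Delta\Delta G = \Delta\Delta G_{query} - \Delta\Delta G_{anchor}}.
#' By default anchors are only eligible for queries in the same UniProt
#' group, and the pair feature is the elementwise difference of the
#' assembled inputs (`X_query - X_anchor`); a concatenation pair feature is
#' available for ablation. Queries with no eligible anchor are not an
#' error: their ids are returned in the `uncovered` attribute.
#'
#' @param data A featurized, partitioned tibble with a `role` column from
#'   [select_anchors()] (or explicit `"query"`/`"anchor"` roles).
#' @param same_group_only Restrict pairing to shared `uniprot_id`
#'   (default `TRUE`).
#' @param pair_feature `"difference"` (default) or `"concatenation"`.
#' @return A tibble with one row per (query, anchor) pair: `query_id`,
#'   `anchor_id`, `uniprot_id`, `anchor_ddg`, `target_dddg` (`NA` when the
#'   query ddG is unknown), and a `pair_feature` matrix column. Attribute
#'   `uncovered` lists query ids without anchors.
#' @export
build_pairs <- function(data, same_group_only = TRUE,
                        pair_feature = c("difference", "concatenation")) {
  pair_feature <- match.arg(pair_feature)
  if (!"role" %in% names(data)) {
    stop_ddg("`data` has no `role` column; run select_anchors() first.")
  }
  X <- feature_matrix(data)
  q_idx <- which(data$role == "query")
  a_idx <- which(data$role == "anchor")
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  uncovered <- character(0)
  for (qi in q_idx) {
    elig <- if (same_group_only) {
      a_idx[data$uniprot_id[a_idx] == data$uniprot_id[qi]]
    } else {
      a_idx
    }
    if (!length(elig)) {
      uncovered <- c(uncovered, data$record_id[qi])
    } else {
      pairs_i <- c(pairs_i, rep(qi, length(elig)))
      pairs_j <- c(pairs_j, elig)
    }
  }
  out <- pair_table(data, X, pairs_i, pairs_j, pair_feature)
  attr(out, "uncovered") <- uncovered
  attr(out, "pair_feature") <- pair_feature
  out
}

#' Build training pairs from labelled records
#'
#' Enumerates ordered record pairs (i, j), i != j, with targets
#' `ddg_i - ddg_j`, for training the pairwise regressor. Pairs are ordered
#' (both directions kept) so antisymmetry of the target is learnable. By
#' default pairing is restricted within UniProt groups — the construction
#' under which group-level label offsets cancel exactly — with global
#' pairing behind a flag for random-split experiments. A seeded cap limits
#' the quadratic blow-up in large groups.
#'
#' @param data A featurized tibble with finite `ddg`; if a `subset` column
#'   is present only training rows are used.
#' @param within_group_only Pair only records sharing `uniprot_id`
#'   (default `TRUE`).
#' @param max_pairs_per_group Optional cap; a seeded uniform subsample of at
#'   most this many pairs is kept per group (or in total when
#'   `within_group_only = FALSE`). `NULL` (default) keeps all pairs.
#' @param seed Seed for the cap subsample; required when capping.
#' @inheritParams build_pairs
#' @return A pair tibble as in [build_pairs()] with finite `target_dddg`.
#' @export
build_training_pairs <- function(data, within_group_only = TRUE,
                                 max_pairs_per_group = NULL, seed = NULL,
                                 pair_feature = c("difference", "concatenation")) {
  pair_feature <- match.arg(pair_feature)
  if ("subset" %in% names(data)) data <- data[data$subset == "train", ]
  if (any(!is.finite(data$ddg))) {
    stop_ddg("training pairs need finite ddg labels for every record.")
  }
  X <- feature_matrix(data)
  idx_groups <- if (within_group_only) {
    split(seq_len(nrow(data)), data$uniprot_id)
  } else {
    list(all = seq_len(nrow(data)))
  }
  if (!is.null(max_pairs_per_group) && is.null(seed)) {
    stop_ddg("`seed` is required when `max_pairs_per_group` is set.")
  }
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (g in seq_along(idx_groups)) {
    ii <- idx_groups[[g]]
    k <- length(ii)
    if (k < 2L) next
    grid_i <- rep(ii, each = k)
    grid_j <- rep(ii, times = k)
    keep <- grid_i != grid_j
    gi <- grid_i[keep]; gj <- grid_j[keep]
    if (!is.null(max_pairs_per_group) && length(gi) > max_pairs_per_group) {
      take <- with_local_seed(seed + g, sample.int(length(gi), max_pairs_per_group))
      gi <- gi[take]; gj <- gj[take]
    }
    pairs_i <- c(pairs_i, gi)
    pairs_j <- c(pairs_j, gj)
  }
  out <- pair_table(data, X, pairs_i, pairs_j, pair_feature)
  attr(out, "pair_feature") <- pair_feature
  out
}

pair_table <- function(data, X, i, j, pair_feature) {
  pf <- if (pair_feature == "difference") {
    X[i, , drop = FALSE] - X[j, , drop = FALSE]
  } else {
    cbind(X[i, , drop = FALSE], X[j, , drop = FALSE])
  }
  rownames(pf) <- NULL
  out <- tibble(
    query_id = data$record_id[i],
    anchor_id = data$record_id[j],
    uniprot_id = ifelse(data$uniprot_id[i] == data$uniprot_id[j],
                        data$uniprot_id[i], NA_character_),
    anchor_ddg = data$ddg[j],
    target_dddg = data$ddg[i] - data$ddg[j]
  )
  out$pair_feature <- pf
  out
}

#' Recover per-query ddG from pairwise predictions
#'
#' Ensemble recovery of the query's binding free energy change from its N
#' anchor-specific pairwise predictions:
#' \deqn{\Delta\Delta G_{query} = \frac{1}{N} \sum_i
#'   (\Delta\Delta\Delta G_{pred,i} + \Delta\Delta G_{anchor,i}).}
#' Averaging over anchors guards against single-reference bias; the spread
#' of the per-anchor values is reported as a dispersion diagnostic (it is
#' exactly 0 under an oracle pairwise regressor).
#'
#' @param data A tibble with one row per (query, anchor) prediction,
#'   containing the columns named by `query`, `pred` and `anchor`.
#' @param query,pred,anchor Column names (tidy-eval) holding the query id,
#'   the predicted dddG and the anchor's experimental ddG. Defaults match
#'   the output of [build_pairs()] with an added `pred_dddg` column.
#' @return A tibble with one row per query: `query_id` (named as the input
#'   column), `ddg_pred`, `n_anchors`, `anchor_sd` (SD of the per-anchor
#'   recovered values, `NA` for a single anchor), and a `per_anchor` list
#'   column retaining the individual values.
#' @examples
#' d <- tibble::tibble(query_id = "q", pred_dddg = c(0.5, -0.5),
#'                     anchor_ddg = c(1, 2))
#' recover_query_ddg(d)  # ddg_pred 1.5
#' @export
recover_query_ddg <- function(data, query = "query_id", pred = "pred_dddg",
                              anchor = "anchor_ddg") {
  for (col in c(query, pred, anchor)) {
    if (!col %in% names(data)) stop_ddg("column `", col, "` not found.")
  }
  if (!nrow(data)) stop_ddg("no pairwise predictions supplied (query uncovered).")
  if (any(!is.finite(data[[pred]])) || any(!is.finite(data[[anchor]]))) {
    stop_ddg("predictions and anchor ddG values must be finite.")
  }
  per <- split(data[[pred]] + data[[anchor]], data[[query]])
  out <- tibble(
    query_id = names(per),
    ddg_pred = unname(vapply(per, mean, numeric(1))),
    n_anchors = unname(vapply(per, length, integer(1))),
    anchor_sd = unname(vapply(per, function(v) if (length(v) > 1) sd(v) else NA_real_,
                              numeric(1)))
  )
  out$per_anchor <- unname(per)
  names(out)[1] <- query
  # preserve the query order of first appearance
  out[match(unique(data[[query]]), out[[query]]), ]
}

#' Write pairs to disk
#'
#' TSV of (`query_id`, `anchor_id`, `target_dddg`) plus the pair feature
#' matrix written alongside via [write_features()] conventions.
#'
#' @param pairs A pair tibble from [build_pairs()] or
#'   [build_training_pairs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(
    tibble(query_id = pairs$query_id, anchor_id = pairs$anchor_id,
           target_dddg = pairs$target_dddg),
    path, progress = FALSE
  )
  invisible(path)
}
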