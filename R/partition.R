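#' Random 8:1:1 dataset partition
#'
#' Assigns every record to train/val/test by a seeded uniform shuffle using
#' the deterministic size rule: `train = floor(0.8 n)`, the remainder `m`
#' split as `val = floor(m/2)`, `test = m - val`. On 4179 records this
#' yields the canonical 3343/418/418 split. The same seed always produces
#' the identical assignment.
#'
#' @param data A mutation record tibble.
#' @param seed Integer seed controlling the shuffle.
#' @param ratios Length-3 numeric vector of train/val/test proportions
#'   (default `c(0.8, 0.1, 0.1)`); `val`/`test` share the remainder in
#'   proportion `ratios[2] : ratios[3]`.
#' @return `data` with an added factor column `subset` (levels train, val,
#'   test) and a `ddg_split` attribute (strategy, seed, ratios, sizes).
#' @export
partition_random <- function(data, seed, ratios = c(0.8, 0.1, 0.1)) {
  n <- nrow(data)
  if (n < 3L) stop_ddg("need at least 3 records to partition, got ", n)
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) <= 0) {
    stop_ddg("`ratios` must be three non-negative proportions.")
  }
  ratios <- ratios / sum(ratios)
  n_train <- floor(ratios[1] * n)
  m <- n - n_train
  n_val <- floor(m * ratios[2] / (ratios[2] + ratios[3]))
  n_test <- m - n_val
  perm <- with_local_seed(seed, sample.int(n))
  subset <- character(n)
  subset[perm[seq_len(n_train)]] <- "train"
  subset[perm[n_train + seq_len(n_val)]] <- "val"
  subset[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  data$subset <- factor(subset, levels = c("train", "val", "test"))
  attr(data, "ddg_split") <- list(
    strategy = "random", seed = as.integer(seed), ratios = ratios,
    sizes = c(train = n_train, val = n_val, test = n_test)
  )
  data
}

#' UniProt-grouped dataset partition
#'
#' Partitions at the protein level so that no UniProt group is shared
#' between train, val and test — the leakage-aware split that probes
#' generalization to unseen proteins. Groups are shuffled with the seed;
#' the first `floor(0.8 G)` groups go to train and the remaining groups are
#' assigned alternately to val and test (val first by default). All records
#' inherit their group's subset, so group sizes — not record counts — are
#' balanced.
#'
#' @param data A mutation record tibble with `uniprot_id`.
#' @param seed Integer seed controlling the group shuffle.
#' @param val_first Assign the first leftover group to val (default).
#'   When only one group is left over (fewer than 6 groups in total) the
#'   default leaves the test set empty, which is an error; either supply
#'   at least 6 groups or set `val_first = FALSE` to give the single
#'   leftover group to test.
#' @return `data` with a `subset` factor column and a `ddg_split` attribute
#'   that also records the group assignment.
#' @export
partition_by_uniprot <- function(data, seed, val_first = TRUE) {
  groups <- unique(data$uniprot_id)
  G <- length(groups)
  if (G < 3L) stop_ddg("need at least 3 distinct uniprot groups, got ", G)
  perm <- with_local_seed(seed, sample(groups))
  n_train <- floor(0.8 * G)
  rest <- perm[-seq_len(n_train)]
  first <- if (val_first) "val" else "test"
  second <- if (val_first) "test" else "val"
  rest_subset <- rep(c(first, second), length.out = length(rest))
  assignment <- c(setNames(rep("train", n_train), perm[seq_len(n_train)]),
                  setNames(rest_subset, rest))
  if (!any(assignment == "test")) {
    stop_ddg("uniprot split leaves the test set empty with ", G,
             " groups; use at least 6 groups or set val_first = FALSE.")
  }
  data$subset <- factor(unname(assignment[data$uniprot_id]),
                        levels = c("train", "val", "test"))
  attr(data, "ddg_split") <- list(
    strategy = "uniprot", seed = as.integer(seed),
    ratios = c(0.8, 0.1, 0.1),
    sizes = table(data$subset),
    groups = assignment
  )
  data
}

#' Select anchors from the test set
#'
#' Splits the test records into an anchor set (records whose experimental
#' ddG is treated as known reference data) and a query set (records to
#' predict). With `stratified = TRUE` (default) `round(ratio * n_g)`
#' anchors are drawn per UniProt group, so every query group with at least
#' `ceiling(1/ratio)` members is guaranteed an anchor; with
#' `stratified = FALSE` sampling is pooled across the whole test set.
#' Rounding is half-up.
#'
#' @param data A partitioned tibble (column `subset` present).
#' @param ratio Anchor fraction in `[0, 0.9]`; 0 selects no anchors.
#' @param seed Integer seed for the draw.
#' @param stratified Stratify the draw by `uniprot_id` (default `TRUE`).
#' @return `data` with an added character column `role`: `"anchor"` or
#'   `"query"` for test rows, `NA` elsewhere; attribute `ddg_anchor`
#'   records ratio, seed and counts.
#' @export
select_anchors <- function(data, ratio, seed, stratified = TRUE) {
  if (!"subset" %in% names(data)) {
    stop_ddg("`data` has no `subset` column; partition it first.")
  }
  assert_scalar_number(ratio, "ratio")
  if (ratio < 0 || ratio > 0.9) {
    stop_ddg("`ratio` must lie in [0, 0.9], got ", ratio)
  }
  test_idx <- which(data$subset == "test")
  anchor_idx <- integer(0)
  if (ratio > 0 && length(test_idx)) {
    if (stratified) {
      anchor_idx <- with_local_seed(seed, {
        unlist(lapply(split(test_idx, data$uniprot_id[test_idx]), function(ii) {
          k <- round_half_up(ratio * length(ii))
          if (k > 0) sample(ii, k) else integer(0)
        }), use.names = FALSE)
      })
    } else {
      k <- round_half_up(ratio * length(test_idx))
      anchor_idx <- with_local_seed(seed, sample(test_idx, k))
    }
  }
  role <- rep(NA_character_, nrow(data))
  role[test_idx] <- "query"
  role[anchor_idx] <- "anchor"
  data$role <- role
  attr(data, "ddg_anchor") <- list(
    ratio = ratio, seed = as.integer(seed), stratified = stratified,
    n_anchor = length(anchor_idx),
    n_query = length(test_idx) - length(anchor_idx)
  )
  data
}

#' Train/test similarity (leakage) report
#'
#' Quantifies how close each test record sits to the training set, the
#' diagnostic that explains why random splits look optimistic. For every
#' test record it reports the maximum protein sequence identity to any
#' training record, as percent `100 * (1 - edit_distance / max(length))`
#' on the mutant sequences, and the maximum ligand similarity as percent
#' Tanimoto on fingerprints. These are declared substitutes for
#' alignment-based identity and any particular fingerprint similarity, not
#' reproductions of a specific tool.
#'
#' @param data A partitioned mutation tibble (column `subset`).
#' @param fingerprint_backend Passed to [ligand_fingerprint()]; defaults to
#'   `"hashed"` so the report has no cheminformatics dependency.
#' @return A tibble of class `ddg_leakage`, one row per test record:
#'   `record_id`, `max_seq_identity`, `closest_train_record`,
#'   `max_smiles_tanimoto`. Use [glance()] for the min/median/max summary.
#' @export
leakage_report <- function(data,
                           fingerprint_backend = c("hashed", "cheminformatics")) {
  fingerprint_backend <- match.arg(fingerprint_backend)
  if (!"subset" %in% names(data)) {
    stop_ddg("`data` has no `subset` column; partition it first.")
  }
  data <- fill_mutant_seq(data)
  train <- data[data$subset == "train", ]
  test <- data[data$subset == "test", ]
  if (!nrow(train) || !nrow(test)) {
    stop_ddg("both train and test subsets must be non-empty.")
  }

  ed <- adist(test$mutant_seq, train$mutant_seq)
  len_max <- outer(nchar(test$mutant_seq), nchar(train$mutant_seq), pmax)
  identity <- 100 * (1 - ed / len_max)
  best <- max.col(identity, ties.method = "first")

  fp_test <- ligand_fingerprint(test$smiles, backend = fingerprint_backend)
  fp_train <- ligand_fingerprint(train$smiles, backend = fingerprint_backend)
  tani <- 100 * tanimoto_similarity(fp_test, fp_train)

  out <- tibble(
    record_id = test$record_id,
    max_seq_identity = apply(identity, 1, max),
    closest_train_record = train$record_id[best],
    max_smiles_tanimoto = apply(tani, 1, max)
  )
  class(out) <- c("ddg_leakage", class(out))
  attr(out, "strategy") <- attr(data, "ddg_split")$strategy
  out
}

#' @describeIn leakage_report Min/median/max of both similarity measures.
#' @param x A `ddg_leakage` tibble.
#' @param ... Unused.
#' @method glance ddg_leakage
#' @export
glance.ddg_leakage <- function(x, ...) {
  tibble(
    strategy = attr(x, "strategy") %||% NA_character_,
    n_test = nrow(x),
    seq_identity_min = min(x$max_seq_identity),
    seq_identity_median = stats::median(x$max_seq_identity),
    seq_identity_max = max(x$max_seq_identity),
    tanimoto_min = min(x$max_smiles_tanimoto),
    tanimoto_median = stats::median(x$max_smiles_tanimoto),
    tanimoto_max = max(x$max_smiles_tanimoto)
  )
}

#' Write a split assignment to disk
#'
#' Two-column TSV (`record_id`, `subset`) plus a JSON metadata sidecar
#' recording strategy, seed, ratios and sizes.
#'
#' @param data A partitioned tibble.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_split <- function(data, path) {
  if (!"subset" %in% names(data)) stop_ddg("`data` has no `subset` column.")
  readr::write_tsv(tibble(record_id = data$record_id,
                          subset = as.character(data$subset)),
                   path, progress = FALSE)
  meta <- attr(data, "ddg_split")
  meta$sizes <- as.list(meta$sizes)
  meta$groups <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
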