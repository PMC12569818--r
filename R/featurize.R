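#' Protein feature combination
#'
#' Two ways of combining the mutant and wild-type embedding vectors into a
#' single protein feature: `protein_feature_difference()` returns the
#' elementwise difference `r_mut - r_wt`, which isolates the embedding shift
#' caused by the mutation; `protein_feature_concat()` returns the
#' concatenation `[r_mut, r_wt]` (mutant first), twice as long.
#'
#' @param r_mut,r_wt Numeric vectors (or matrices with one embedding per
#'   row) of equal dimension.
#' @return A numeric vector/matrix: same dimension as the inputs for the
#'   difference, doubled for the concatenation.
#' @export
protein_feature_difference <- function(r_mut, r_wt) {
  check_same_dim(r_mut, r_wt)
  r_mut - r_wt
}

#' @rdname protein_feature_difference
#' @export
protein_feature_concat <- function(r_mut, r_wt) {
  check_same_dim(r_mut, r_wt)
  if (is.matrix(r_mut)) cbind(r_mut, r_wt) else c(r_mut, r_wt)
}

check_same_dim <- function(r_mut, r_wt) {
  dm <- if (is.matrix(r_mut)) ncol(r_mut) else length(r_mut)
  dw <- if (is.matrix(r_wt)) ncol(r_wt) else length(r_wt)
  if (dm != dw) {
    stop_ddg("embedding dimension mismatch: ", dm, " vs ", dw)
  }
  invisible(TRUE)
}

#' Assemble the model input vector
#'
#' Joins a protein feature (difference or concatenation of embeddings) with
#' a ligand fingerprint into the final model input `[x_protein, x_ligand]`.
#' With the default 1280-dimensional embeddings and 1024-bit fingerprints
#' the assembled length is 2304 in difference mode and 3584 in
#' concatenation mode.
#'
#' @param x_protein Numeric vector (or matrix, one row per record): the
#'   combined protein feature.
#' @param x_ligand Binary fingerprint vector (or matrix).
#' @param embedding_dim Dimension of a single protein embedding; used to
#'   infer and record whether `x_protein` is a difference (`dim`) or a
#'   concatenation (`2 * dim`). Any other length is an error.
#' @return The assembled numeric vector/matrix with attribute `mode` set to
#'   `"difference"` or `"concatenation"`.
#' @export
assemble_input <- function(x_protein, x_ligand, embedding_dim = 1280L) {
  p <- if (is.matrix(x_protein)) ncol(x_protein) else length(x_protein)
  mode <- if (p == embedding_dim) {
    "difference"
  } else if (p == 2L * embedding_dim) {
    "concatenation"
  } else {
    stop_ddg("unexpected protein feature length ", p, "; expected ",
             embedding_dim, " (difference) or ", 2L * embedding_dim,
             " (concatenation).")
  }
  out <- if (is.matrix(x_protein)) {
    cbind(x_protein, x_ligand)
  } else {
    c(x_protein, as.numeric(x_ligand))
  }
  attr(out, "mode") <- mode
  out
}

#' Featurize a mutation dataset
#'
#' Runs the full featurization pipeline on a mutation record tibble: fill
#' mutant sequences from `mutation_spec` where absent, embed wild-type and
#' mutant sequences with the given provider, combine them by difference or
#' concatenation, fingerprint the ligand SMILES, and assemble the final
#' model input per record. The result is the input tibble with an added
#' matrix column `feature` (one row per record), so it pipes directly into
#' [partition_random()], [build_training_pairs()], or [fit_ddg_model()].
#'
#' Featurization is deterministic: the same data and settings always yield
#' the identical matrix.
#'
#' @param data A mutation record tibble (see [mutation-records]).
#' @param mode `"difference"` (default; the combination that best captures
#'   mutation effects) or `"concatenation"`.
#' @param provider Embedding provider; defaults to [synthetic_embedder()].
#' @param fingerprint_backend Passed to [ligand_fingerprint()].
#' @param n_bits,radius Fingerprint settings, see [ligand_fingerprint()].
#' @return `data` with a `feature` matrix column and a `ddg_featurize`
#'   attribute recording provider name, embedding dimension, mode,
#'   fingerprint backend, radius and bit count.
#' @export
featurize_mutation_data <- function(data,
                                    mode = c("difference", "concatenation"),
                                    provider = synthetic_embedder(),
                                    fingerprint_backend = c("cheminformatics", "hashed"),
                                    n_bits = 1024L, radius = 2L) {
  mode <- match.arg(mode)
  fingerprint_backend <- match.arg(fingerprint_backend)
  assert_mutation_data(data)
  data <- fill_mutant_seq(data)

  emb_wt <- embed_sequences(data$wild_seq, provider)
  emb_mut <- embed_sequences(data$mutant_seq, provider)
  x_protein <- if (mode == "difference") {
    protein_feature_difference(emb_mut, emb_wt)
  } else {
    protein_feature_concat(emb_mut, emb_wt)
  }
  x_ligand <- ligand_fingerprint(data$smiles, backend = fingerprint_backend,
                                 n_bits = n_bits, radius = radius)
  feature <- assemble_input(x_protein, x_ligand,
                            embedding_dim = provider$dim)
  attr(feature, "mode") <- NULL
  rownames(feature) <- data$record_id
  data$feature <- feature
  attr(data, "ddg_featurize") <- list(
    provider = provider$name, embedding_dim = provider$dim, mode = mode,
    fingerprint_backend = fingerprint_backend, radius = as.integer(radius),
    n_bits = as.integer(n_bits),
    protein_block = ncol(x_protein), total_dim = ncol(feature)
  )
  data
}

#' Persist a feature matrix with its metadata sidecar
#'
#' Writes the `feature` column of a featurized tibble as a dense TSV (rows
#' in `record_id` order) plus a JSON sidecar describing how the features
#' were built, so downstream runs can refuse to mix incompatible feature
#' spaces.
#'
#' @param data A featurized mutation tibble.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(data, path) {
  m <- feature_matrix(data)
  df <- as.data.frame(m)
  names(df) <- paste0("f", seq_len(ncol(m)))
  df <- cbind(record_id = data$record_id, df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  meta <- attr(data, "ddg_featurize")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
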