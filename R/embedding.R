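#' Synthetic protein sequence embedding
#'
#' Deterministic stand-in for a protein language model encoder: each
#' sequence is mapped to a fixed-length vector of i.i.d. standard normal
#' draws from a PRNG seeded by a stable hash of the sequence (and `salt`).
#' The same sequence always yields the bit-identical vector, on every
#' platform, so the whole featurization pipeline is reproducible with no
#' model download. It carries no biophysical information beyond sequence
#' identity; sequences differing at a single residue receive independent
#' vectors.
#'
#' @param seq Character vector of amino-acid sequences.
#' @param dim Embedding dimension (default 1280, the width of a large
#'   protein language model's last hidden layer).
#' @param salt Integer mixed into the hash, to derive independent embedding
#'   spaces from the same sequences.
#' @return A numeric matrix with `length(seq)` rows and `dim` columns.
#' @seealso [synthetic_embedder()] for the provider object used by
#'   [featurize_mutation_data()].
#' @export
synthetic_embed <- function(seq, dim = 1280L, salt = 0L) {
  if (!is.numeric(dim) || length(dim) != 1L || dim <= 0) {
    stop_ddg("`dim` must be a positive integer.")
  }
  dim <- as.integer(dim)
  if (any(!nzchar(seq) | is.na(seq))) stop_ddg("sequences must be non-empty.")
  out <- matrix(NA_real_, nrow = length(seq), ncol = dim)
  uniq <- unique(seq)
  for (s in uniq) {
    key <- stable_hash(paste0(salt, "|", s))
    v <- with_local_seed(key, rnorm(dim))
    out[seq == s, ] <- matrix(v, nrow = sum(seq == s), ncol = dim, byrow = TRUE)
  }
  rownames(out) <- names(seq)
  out
}

#' Embedding providers
#'
#' An embedding provider is a named object bundling an encoder function with
#' its output dimension. The contract every provider must satisfy: `embed()`
#' is deterministic — the same sequence always yields the identical vector —
#' and returns one finite numeric row per input sequence with exactly `dim`
#' columns. `synthetic_embedder()` returns the default provider backed by
#' [synthetic_embed()]. An adapter around a real protein language model can
#' be supplied as any list with elements `name`, `dim`, and `embed`; how
#' per-residue states are pooled into one vector (mean vs. first-token) is
#' the adapter's documented choice.
#'
#' @param dim Embedding dimension.
#' @param salt Integer salt forwarded to [synthetic_embed()].
#' @return An object of class `ddg_embedder`.
#' @examples
#' p <- synthetic_embedder(dim = 8)
#' p$embed(c("ACDT", "ACDI"))
#' @export
synthetic_embedder <- function(dim = 1280L, salt = 0L) {
  dim <- as.integer(dim)
  if (dim <= 0) stop_ddg("`dim` must be a positive integer.")
  structure(
    list(
      name = "synthetic-gaussian",
      dim = dim,
      salt = as.integer(salt),
      embed = function(seq) synthetic_embed(seq, dim = dim, salt = salt)
    ),
    class = "ddg_embedder"
  )
}

#' @export
print.ddg_embedder <- function(x, ...) {
  cat("<ddg_embedder> ", x$name, " (dim = ", x$dim, ")\n", sep = "")
  invisible(x)
}

#' Embed sequences with a provider
#'
#' @param seq Character vector of sequences.
#' @param provider An embedding provider (see [synthetic_embedder()]).
#' @return Numeric matrix, one row per sequence, `provider$dim` columns.
#' @export
embed_sequences <- function(seq, provider = synthetic_embedder()) {
  m <- provider$embed(seq)
  if (!is.matrix(m) || ncol(m) != provider$dim || nrow(m) != length(seq)) {
    stop_ddg("provider `", provider$name %||% "?",
             "` violated the embedding contract (wrong shape).")
  }
  if (!all(is.finite(m))) {
    stop_ddg("provider `", provider$name %||% "?",
             "` returned non-finite embedding values.")
  }
  m
}
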