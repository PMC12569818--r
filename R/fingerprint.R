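#' Ligand fingerprints
#'
#' Converts SMILES strings into fixed-length binary fingerprints. The
#' `"cheminformatics"` backend computes extended-connectivity (ECFP4,
#' radius 2) circular fingerprints through OpenBabel (ChemmineOB) and folds
#' the native bit vector down to `n_bits` by OR-ing equal-sized blocks —
#' the standard folding used for hashed circular fingerprints. The
#' `"hashed"` backend is a dependency-free deterministic stand-in that
#' hashes all character k-mers (k = 1..4) of the SMILES string into
#' `n_bits` buckets; it preserves identity and rough string similarity but
#' has no chemical meaning, and is intended for tests and synthetic data.
#'
#' @param smiles Character vector of SMILES strings.
#' @param backend `"cheminformatics"` (default) or `"hashed"`.
#' @param n_bits Fingerprint length in bits (default 1024).
#' @param radius Circular fingerprint radius for the cheminformatics
#'   backend (default 2, i.e. ECFP4).
#' @return Integer 0/1 matrix with `length(smiles)` rows and `n_bits`
#'   columns; attribute `backend` records which backend produced it.
#' @examples
#' fp <- ligand_fingerprint(c("CCO", "c1ccccc1"), backend = "hashed")
#' dim(fp)
#' @export
ligand_fingerprint <- function(smiles,
                               backend = c("cheminformatics", "hashed"),
                               n_bits = 1024L, radius = 2L) {
  backend <- match.arg(backend)
  n_bits <- as.integer(n_bits)
  if (n_bits <= 0) stop_ddg("`n_bits` must be positive.")
  if (any(is.na(smiles) | !nzchar(smiles))) {
    stop_ddg("SMILES strings must be non-empty.")
  }
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  uniq <- unique(smiles)
  fps <- if (backend == "cheminformatics") {
    vapply(uniq, ecfp_openbabel, integer(n_bits),
           n_bits = n_bits, radius = radius)
  } else {
    vapply(uniq, hashed_kmer_fp, integer(n_bits), n_bits = n_bits)
  }
  for (j in seq_along(uniq)) {
    hit <- smiles == uniq[j]
    out[hit, ] <- matrix(fps[, j], nrow = sum(hit), ncol = n_bits, byrow = TRUE)
  }
  attr(out, "backend") <- backend
  out
}

ecfp_openbabel <- function(smi, n_bits, radius) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop_ddg("the cheminformatics fingerprint backend requires ChemmineOB; ",
             "use backend = \"hashed\" otherwise.")
  }
  type <- paste0("ECFP", 2L * as.integer(radius))
  bits <- tryCatch(
    ChemmineOB::fingerprint_OB(ChemmineOB::forEachMol("SMILES", smi, identity),
                               type),
    error = function(e) {
      stop_ddg("cannot parse SMILES '", smi, "': ", conditionMessage(e))
    }
  )
  bits <- as.integer(bits)
  if (length(bits) < n_bits) bits <- c(bits, integer(n_bits - length(bits)))
  if (length(bits) %% n_bits != 0L) {
    bits <- c(bits, integer(n_bits - length(bits) %% n_bits))
  }
  folded <- rowSums(matrix(bits, nrow = n_bits)) > 0
  as.integer(folded)
}

hashed_kmer_fp <- function(smi, n_bits) {
  chars <- nchar(smi)
  bits <- integer(n_bits)
  for (k in 1:4) {
    if (chars < k) break
    starts <- seq_len(chars - k + 1L)
    kmers <- substring(smi, starts, starts + k - 1L)
    idx <- vapply(kmers, function(x) stable_hash(x) %% n_bits + 1L, numeric(1))
    bits[unique(as.integer(idx))] <- 1L
  }
  bits
}

#' Tanimoto similarity between binary fingerprints
#'
#' `tanimoto_similarity(a, b)` is the size of the bit intersection divided
#' by the size of the union. Two all-zero fingerprints are defined as
#' identical (similarity 1).
#'
#' @param a,b Binary vectors of equal length, or matrices with one
#'   fingerprint per row (similarity computed row-wise against all rows of
#'   `b`, giving a matrix).
#' @return A similarity in `[0, 1]`, or a matrix of similarities.
#' @export
tanimoto_similarity <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    if (ncol(a) != ncol(b)) stop_ddg("fingerprint lengths differ.")
    inter <- a %*% t(b)
    union <- outer(rowSums(a), rowSums(b), "+") - inter
    out <- ifelse(union == 0, 1, inter / union)
    return(out)
  }
  if (length(a) != length(b)) stop_ddg("fingerprint lengths differ.")
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0) 1 else inter / union
}
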