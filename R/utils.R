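# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
# X tolerated as an unknown residue in input sequences
AA_ALPHABET_X <- c(AA_ALPHABET, "X")

# Polynomial rolling hash of a character string, computed in doubles.
# The modulus is kept below 2^26 so base * hash + byte never exceeds 2^53,
# which makes the result exact and identical on every platform.
poly_hash <- function(x, base, mod) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * base + b) %% mod
  h
}

# Stable integer in [0, 2^31 - 2] from a string; two independent rolling
# hashes are combined so that collisions require a simultaneous collision
# in both.
stable_hash <- function(x) {
  h1 <- poly_hash(x, base = 131, mod = 67108859)   # prime < 2^26
  h2 <- poly_hash(x, base = 137, mod = 33554393)   # prime < 2^25
  (h1 * 33554393 + h2) %% 2147483647
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

# Conventional half-up rounding (R's round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ddg <- function(...) abort(paste0(...), class = "ddganchor_error")

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_ddg("`", name, "` must be a single finite number.")
  }
}

# Extract the feature matrix column from a featurized tibble.
feature_matrix <- function(data, col = "feature") {
  if (!col %in% names(data)) {
    stop_ddg("column `", col, "` not found; run featurize_mutation_data() ",
             "or build_pairs() first.")
  }
  m <- data[[col]]
  if (!is.matrix(m)) stop_ddg("column `", col, "` is not a feature matrix.")
  m
}
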