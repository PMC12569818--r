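# Fixtures built in code; no binary data anywhere.

# A tiny hand-written record table with every canonical column populated.
toy_records <- function() {
  tibble::tibble(
    record_id = c("r1", "r2", "r3"),
    uniprot_id = c("P1", "P1", "P2"),
    wild_seq = c("ACDTGH", "ACDTGH", "MKVLYW"),
    mutation_spec = c("T4I", "A1G+C2A", NA),
    mutant_seq = c(NA, NA, "MKVLYF"),
    smiles = c("CCO", "CCO", "c1ccccc1"),
    ddg = c(0.5, -1.2, 2.3),
    distance = c(3.2, 12.0, 20.5)
  )
}

# Small simulation used by most pipeline tests: low dimension and hashed
# fingerprints keep it fast; the group/shift structure is the same as the
# full-scale benchmark.
small_sim <- function(seed = 1, n_groups = 8, records_per_group = 12,
                      embedding_dim = 64, noise_sd = 0.5,
                      group_offset_sd = 3, ...) {
  simulate_mutation_data(
    n_groups = n_groups, records_per_group = records_per_group,
    seq_len = 30, embedding_dim = embedding_dim,
    fingerprint_backend = "hashed", noise_sd = noise_sd,
    group_offset_sd = group_offset_sd, seed = seed, ...
  )
}

expect_valid_partition <- function(data) {
  expect_true(all(!is.na(data$subset)))
  expect_setequal(levels(data$subset), c("train", "val", "test"))
}
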