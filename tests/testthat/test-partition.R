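fake_ids <- function(n, groups = 1) {
  tibble::tibble(
    record_id = sprintf("r%04d", seq_len(n)),
    uniprot_id = rep_len(sprintf("P%02d", seq_len(groups)), n)
  )
}

test_that("random split sizes follow the floor/remainder rule", {
  # the canonical full-dataset size, plus the small exact cases
  expect_equal(unname(attr(partition_random(fake_ids(4179), seed = 1),
                           "ddg_split")$sizes),
               c(3343, 418, 418))
  s10 <- table(partition_random(fake_ids(10), seed = 1)$subset)
  expect_equal(unname(c(s10)), c(8, 1, 1))
  s12 <- table(partition_random(fake_ids(12), seed = 1)$subset)
  expect_equal(unname(c(s12)), c(9, 1, 2))
  expect_error(partition_random(fake_ids(2), seed = 1), "at least 3")
})

test_that("splits are exhaustive, seed-deterministic and seed-sensitive", {
  d <- fake_ids(50, groups = 10)
  a <- partition_random(d, seed = 42)
  expect_valid_partition(a)
  expect_identical(a$subset, partition_random(d, seed = 42)$subset)
  # over 30 seeds, assignments are essentially always distinct
  assignments <- vapply(1:30, function(s) {
    paste(partition_random(d, seed = s)$subset, collapse = "")
  }, character(1))
  expect_gt(length(unique(assignments)), 28L)

  u <- partition_by_uniprot(d, seed = 42)
  expect_valid_partition(u)
  expect_identical(u$subset, partition_by_uniprot(d, seed = 42)$subset)
})

test_that("uniprot split keeps groups disjoint across subsets", {
  sizes <- c(5, 4, 3, 2, 1)
  d <- tibble::tibble(
    record_id = sprintf("r%02d", 1:15),
    uniprot_id = rep(sprintf("P%d", 1:5), sizes)
  )
  # 5 groups leave a single leftover group: it must go to test
  u <- partition_by_uniprot(d, seed = 3, val_first = FALSE)
  tab <- table(u$uniprot_id, u$subset)
  expect_true(all(rowSums(tab > 0) == 1))  # each group in exactly one subset
  # record counts per subset equal the sum of their member-group sizes,
  # recomputed independently from the same seeded shuffle
  groups <- unique(d$uniprot_id)
  perm <- withr::with_seed(3L, sample(groups),
                           .rng_kind = "Mersenne-Twister",
                           .rng_normal_kind = "Inversion",
                           .rng_sample_kind = "Rejection")
  expected_train <- sum(sizes[match(perm[1:4], groups)])
  expect_equal(sum(u$subset == "train"), expected_train)

  # 10 equal groups -> 8/1/1 groups
  d10 <- fake_ids(40, groups = 10)
  u10 <- partition_by_uniprot(d10, seed = 1)
  tab10 <- table(unique(as.data.frame(u10[, c("uniprot_id", "subset")]))$subset)
  expect_equal(unname(c(tab10)), c(8, 1, 1))
})

test_that("3-group uniprot split errors helpfully; val_first flag swaps", {
  d <- fake_ids(9, groups = 3)
  expect_error(partition_by_uniprot(d, seed = 1), "val_first")
  u <- partition_by_uniprot(d, seed = 1, val_first = FALSE)
  expect_equal(sum(u$subset == "test") > 0, TRUE)
  expect_equal(sum(u$subset == "val"), 0L)
})

test_that("anchor selection counts follow the per-group rounding rule", {
  d <- fake_ids(100)
  d$uniprot_id <- "P1"
  d <- partition_random(d, seed = 1, ratios = c(0, 0, 1))  # everything test
  a0 <- select_anchors(d, ratio = 0, seed = 1)
  expect_equal(sum(a0$role == "anchor", na.rm = TRUE), 0L)
  expect_equal(sum(a0$role == "query", na.rm = TRUE), 100L)

  a3 <- select_anchors(d, ratio = 0.3, seed = 1)
  expect_equal(sum(a3$role == "anchor", na.rm = TRUE), 30L)
  expect_equal(sum(a3$role == "query", na.rm = TRUE), 70L)

  # stratified: groups of (50, 30, 20) at ratio 0.2 -> (10, 6, 4)
  d2 <- tibble::tibble(
    record_id = sprintf("r%03d", 1:100),
    uniprot_id = rep(c("A", "B", "C"), c(50, 30, 20)),
    subset = factor("test", levels = c("train", "val", "test"))
  )
  s <- select_anchors(d2, ratio = 0.2, seed = 9)
  counts <- table(s$uniprot_id[s$role == "anchor"])
  expect_equal(unname(c(counts)), c(10, 6, 4))

  expect_error(select_anchors(d2, ratio = 0.95, seed = 1), "0.9")
  expect_error(select_anchors(d2, ratio = -0.1, seed = 1), "0.9")
})

test_that("leakage report computes percent identity and tanimoto", {
  d <- tibble::tibble(
    record_id = c("t1", "t2", "tr1", "tr2"),
    uniprot_id = c("P1", "P2", "P1", "P2"),
    wild_seq = c("AAAA", "MKVL", "AAAA", "MKVL"),
    mutation_spec = NA_character_,
    mutant_seq = c("AAAA", "MKVI", "AAAT", "MKVI"),
    smiles = c("CCO", "CCN", "CCO", "CCCC"),
    ddg = c(1, 2, 3, 4),
    distance = NA_real_,
    subset = factor(c("test", "test", "train", "train"),
                    levels = c("train", "val", "test"))
  )
  rep_ <- leakage_report(d)
  # t1: identical sequence "AAAA" vs train "AAAT" -> closest is 75; but
  # train also holds "MKVI" (identity 0): the max must be 75
  expect_equal(rep_$max_seq_identity[rep_$record_id == "t1"], 75)
  # t2's mutant "MKVI" appears verbatim in train -> 100% identity
  expect_equal(rep_$max_seq_identity[rep_$record_id == "t2"], 100)
  # t1's SMILES appears verbatim in train -> 100% tanimoto
  expect_equal(rep_$max_smiles_tanimoto[rep_$record_id == "t1"], 100)
  g <- glance(rep_)
  expect_equal(g$seq_identity_max, 100)
  expect_equal(g$n_test, 2L)
})

test_that("grouped splitting lowers test-to-train sequence identity", {
  # families of near-duplicate sequences: random splits scatter a family
  # across train and test, grouped splits keep it together
  sim <- small_sim(seed = 5, n_groups = 8, records_per_group = 10)
  d <- sim$data
  r <- glance(leakage_report(partition_random(d, seed = 11)))
  u <- glance(leakage_report(partition_by_uniprot(d, seed = 11)))
  expect_gt(r$seq_identity_median, 90)  # same-family mutants in train
  expect_lt(u$seq_identity_max, r$seq_identity_median)
  expect_lt(u$seq_identity_median, 60)  # only cross-family identity remains
})

test_that("split files round-trip through write_split", {
  d <- partition_random(fake_ids(20), seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split(d, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$subset, as.character(d$subset))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$strategy, "random")
  expect_equal(meta$seed, 2L)
})
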