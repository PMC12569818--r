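# A tiny featurized table with explicit roles for pairing tests.
pair_fixture <- function() {
  d <- tibble::tibble(
    record_id = c("q1", "q2", "a1", "a2", "a3", "x1"),
    uniprot_id = c("P1", "P1", "P1", "P1", "P1", "P2"),
    ddg = c(2.0, -1.0, 0.5, 1.5, -0.5, 3.0),
    subset = factor("test", levels = c("train", "val", "test")),
    role = c("query", "query", "anchor", "anchor", "anchor", "query")
  )
  d$feature <- matrix(seq_len(6 * 4), nrow = 6, ncol = 4)
  d
}

test_that("build_pairs enumerates query x same-group anchors", {
  d <- pair_fixture()
  pairs <- build_pairs(d)
  expect_identical(nrow(pairs), 6L)  # 2 queries x 3 anchors
  expect_setequal(attr(pairs, "uncovered"), "x1")  # no P2 anchors

  # pair features are elementwise differences of the assembled inputs
  i <- which(pairs$query_id == "q1" & pairs$anchor_id == "a1")
  expect_equal(pairs$pair_feature[i, ], d$feature[1, ] - d$feature[3, ])
  # targets are ddg_query - ddg_anchor
  one_anchor <- pairs[pairs$anchor_id == "a1", ]
  expect_equal(one_anchor$target_dddg[match(c("q1", "q2"), one_anchor$query_id)],
               c(1.5, -1.5))

  # without the group restriction the P2 query is covered too
  all_pairs <- build_pairs(d, same_group_only = FALSE)
  expect_identical(nrow(all_pairs), 9L)
  expect_length(attr(all_pairs, "uncovered"), 0L)
})

test_that("a record paired with itself gives zero feature and target", {
  d <- pair_fixture()
  d$role <- c("query", "anchor", "anchor", "anchor", "anchor", "anchor")
  d$record_id[2] <- "q1_dup"
  d$ddg[2] <- d$ddg[1]
  d$feature[2, ] <- d$feature[1, ]
  pairs <- build_pairs(d)
  i <- which(pairs$anchor_id == "q1_dup")
  expect_true(all(pairs$pair_feature[i, ] == 0))
  expect_equal(pairs$target_dddg[i], 0)
})

test_that("training pairs enumerate ordered within-group pairs", {
  d <- tibble::tibble(
    record_id = sprintf("r%d", 1:5),
    uniprot_id = c("A", "A", "A", "B", "B"),
    ddg = c(1, 2, 4, 0, 3)
  )
  d$feature <- matrix(rnorm(5 * 3), nrow = 5)
  pairs <- build_training_pairs(d)
  expect_identical(nrow(pairs), 6L + 2L)  # 3*2 + 2*1 ordered pairs

  # antisymmetry: target(i,j) == -target(j,i)
  key <- paste(pairs$query_id, pairs$anchor_id)
  rev_key <- paste(pairs$anchor_id, pairs$query_id)
  expect_equal(pairs$target_dddg, -pairs$target_dddg[match(key, rev_key)])

  # k records in one group -> k(k-1) ordered pairs
  one <- build_training_pairs(d[d$uniprot_id == "A", ])
  expect_identical(nrow(one), 6L)

  # global pairing spans groups
  glob <- build_training_pairs(d, within_group_only = FALSE)
  expect_identical(nrow(glob), 20L)

  # the seeded cap subsamples deterministically
  capped <- build_training_pairs(d, max_pairs_per_group = 4, seed = 1)
  expect_identical(nrow(capped), 4L + 2L)
  expect_identical(capped, build_training_pairs(d, max_pairs_per_group = 4, seed = 1))
  expect_error(build_training_pairs(d, max_pairs_per_group = 4), "seed")
})

test_that("recover_query_ddg implements the ensemble-mean recovery", {
  d <- tibble::tibble(query_id = "q", pred_dddg = c(0.5, -0.5),
                      anchor_ddg = c(1.0, 2.0))
  r <- recover_query_ddg(d)
  expect_equal(r$ddg_pred, 1.5)
  expect_identical(r$n_anchors, 2L)
  expect_equal(r$per_anchor[[1]], c(1.5, 1.5))
  expect_equal(r$anchor_sd, 0)

  # single anchor, zero predicted difference -> the anchor's value
  r1 <- recover_query_ddg(tibble::tibble(query_id = "q", pred_dddg = 0,
                                         anchor_ddg = 0.7))
  expect_equal(r1$ddg_pred, 0.7)
  expect_true(is.na(r1$anchor_sd))

  expect_error(recover_query_ddg(d[0, ]), "uncovered")
  expect_error(recover_query_ddg(tibble::tibble(query_id = "q",
                                                pred_dddg = NA_real_,
                                                anchor_ddg = 1)), "finite")
})

test_that("oracle pairwise predictions recover true ddG exactly", {
  # algebraic identity: pred_i = ddg_q - ddg_a_i implies recovery == ddg_q
  set.seed(1)
  for (rep in 1:20) {
    n_anchor <- sample(1:8, 1)
    ddg_q <- rnorm(1, 0, 2)
    ddg_a <- rnorm(n_anchor, 0, 2)
    r <- recover_query_ddg(tibble::tibble(
      query_id = "q", pred_dddg = ddg_q - ddg_a, anchor_ddg = ddg_a
    ))
    expect_equal(r$ddg_pred, ddg_q, tolerance = 1e-12)
    if (n_anchor > 1) expect_equal(r$anchor_sd, 0, tolerance = 1e-12)
  }
})

test_that("within-group pair targets cancel group offsets", {
  sim <- small_sim(seed = 3, n_groups = 4, records_per_group = 6)
  pairs <- build_training_pairs(sim$data)
  # oracle dddG within a group is independent of the group offset b_g:
  # it must equal w . (X_q - X_a) exactly
  w <- sim$truth$weights
  expect_equal(
    as.numeric(pairs$pair_feature %*% w),
    oracle_predict(sim$truth, sim$data)[match(pairs$query_id, sim$data$record_id)] -
      oracle_predict(sim$truth, sim$data)[match(pairs$anchor_id, sim$data$record_id)],
    tolerance = 1e-10
  )
})
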