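test_that("log pseudo-likelihood evaluates the printed part counts termwise", {
  # a part concentrated on one symbol contributes zero
  expect_equal(log_pseudo_likelihood(matrix(c(10, 0), 1)), 0)

  em <- example_partition_model()
  agg <- aggregate_counts(em$counts, em$partition)
  manual <- 120 * log(0.6) + 80 * log(0.4) +
    75 * log(0.5) + 75 * log(0.5) +
    10 * log(0.25) + 30 * log(0.75)
  expect_equal(log_pseudo_likelihood(agg), manual, tolerance = 1e-12)

  # merging parts with identical empirical rows leaves the value unchanged
  two <- matrix(c(30, 10, 60, 20), 2, byrow = TRUE)
  merged <- matrix(c(90, 30), 1)
  expect_equal(log_pseudo_likelihood(two), log_pseudo_likelihood(merged),
               tolerance = 1e-12)
})

test_that("BIC decomposes exactly with the (|A|-1)|L|/2 ln n penalty", {
  em <- example_partition_model()
  b3 <- bic_value(em$counts, em$partition)
  expect_equal(b3$penalty, 3 / 2 * log(393), tolerance = 1e-12)
  expect_equal(b3$bic, b3$log_pseudo_likelihood - b3$penalty)
  expect_lte(b3$log_pseudo_likelihood, 0)

  singl <- partition(1:8, em$counts$states)
  b8 <- bic_value(em$counts, singl)
  expect_equal(b8$penalty, 8 / 2 * log(393), tolerance = 1e-12)

  # merging identical-row parts strictly increases the BIC
  ab <- alphabet(c("0", "1"))
  x <- rep(c("0", "0", "1"), length.out = 900)
  ct <- count_transitions(x, ab, 2)
  st <- ct$states
  same <- which(rowSums(ct$counts) > 0)[1:2]
  ct2 <- ct
  ct2$counts[same[2], ] <- ct2$counts[same[1], ]
  lab <- seq_along(st)
  merged_lab <- lab
  merged_lab[same[2]] <- merged_lab[same[1]]
  expect_gt(bic_value(ct2, partition(merged_lab, st))$bic,
            bic_value(ct2, partition(lab, st))$bic)

  expect_error(bic_value(em$counts, em$partition, n = 1), "exceed 1")
})

test_that("states with identical high-count rows are merged by the agglomeration", {
  ab <- alphabet(c("0", "1"))
  st <- enumerate_states(ab, model_spec(2))
  mat <- matrix(c(120, 40,
                  120, 40,
                  30, 130,
                  30, 130), 4, byrow = TRUE,
                dimnames = list(as.character(st), c("0", "1")))
  ct <- structure(list(counts = mat, marginals = rowSums(mat), n = 643L,
                       alphabet = ab, spec = model_spec(2),
                       states = as.character(st)),
                  class = "pmm_counts")
  est <- estimate_partition(ct)
  expect_equal(est$n_parts, 2)
  expect_identical(est$parts[[1]], c("00", "01"))
  expect_identical(est$parts[[2]], c("10", "11"))
})

test_that("greedy agglomeration dominates the trivial partitions and respects the oracle", {
  for (seed in 1:6) {
    ct <- random_count_table(seed, m = 2L, o = 2L, n = 500L)
    est <- estimate_partition(ct)
    got <- attr(est, "bic")$bic
    expect_gte(got, bic_value(ct, partition(1:4, ct$states))$bic - 1e-9)
    expect_gte(got, bic_value(ct, partition(rep(1, 4), ct$states))$bic - 1e-9)
    expect_lte(got, attr(exhaustive_partition_search(ct), "bic")$bic + 1e-9)
  }
})

test_that("iid sequences collapse to a single part", {
  ab <- alphabet(c("0", "1"))
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(c("0", "1"), 5000, replace = TRUE, prob = c(0.35, 0.65))
    est <- estimate_partition(count_transitions(x, ab, 2))
    hits <- hits + (est$n_parts == 1L)
  }
  expect_gte(hits, 9L)
})

test_that("unobserved states are retained, flagged, and attached for serialisation", {
  ab <- alphabet(c("a", "b"))
  x <- rep(c("a", "b"), 60) # 'aa' and 'bb' never occur at order 2
  ct <- count_transitions(x, ab, 2)
  est <- estimate_partition(ct)
  expect_setequal(attr(est, "observed"), c("ab", "ba"))
  expect_length(est$index_of, 4)
  # every state is assigned a valid part index
  expect_true(all(est$index_of %in% seq_len(est$n_parts)))
})

test_that("the plug-in entropy equals -ln ML / (n ln D) and its weighted form", {
  for (seed in 11:16) {
    ct <- random_count_table(seed, m = 3L, o = 1L, n = 400L)
    est <- estimate_partition(ct)
    h <- entropy_plugin(ct, est, D = 2)
    agg <- aggregate_counts(ct, est)
    expect_equal(h$value,
                 -log_pseudo_likelihood(agg) / (ct$n * log(2)),
                 tolerance = 1e-12)
    # independent weighted plug-in form
    marg <- rowSums(agg)
    rows <- agg[marg > 0, , drop = FALSE] / marg[marg > 0]
    hl <- apply(rows, 1, function(r) entropy2(r))
    expect_equal(h$value, sum(marg[marg > 0] / ct$n * hl), tolerance = 1e-10)
    # bounded by the log alphabet size
    expect_gte(h$value, 0)
    expect_lte(h$value, log2(3) + 1e-12)
  }
})

test_that("deterministic sequences have zero estimated entropy", {
  ab <- alphabet(c("a", "b"))
  x <- rep(c("a", "b"), 100)
  ct <- count_transitions(x, ab, 1)
  est <- estimate_partition(ct)
  expect_equal(entropy_plugin(ct, est)$value, 0)
})

test_that("an iid uniform binary sample estimates one bit per symbol", {
  set.seed(99)
  ab <- alphabet(c("0", "1"))
  x <- sample(c("0", "1"), 2e4, replace = TRUE)
  ct <- count_transitions(x, ab, 1)
  est <- estimate_partition(ct)
  expect_equal(entropy_plugin(ct, est)$value, 1, tolerance = 0.02)
  # the transitions denominator differs only by the o/n correction
  expect_equal(entropy_plugin(ct, est, denominator = "transitions")$value,
               entropy_plugin(ct, est)$value * ct$n / (ct$n - 1),
               tolerance = 1e-12)
})

test_that("the closed-form entropy matches the state-level conditional entropy", {
  expect_equal(entropy_closed_form(
    pmm(alphabet(c("a", "c", "g", "t")), model_spec(1),
        partition(rep(1, 4), enumerate_states(alphabet(c("a", "c", "g", "t")), 1)),
        matrix(0.25, 1, 4), part_weights = 1), D = 4)$value, 1)

  # a three-part model: part-level and state-level computations agree
  ab <- alphabet(c("0", "1"))
  st <- enumerate_states(ab, model_spec(2))
  part <- partition(c(1, 2, 2, 3), st)
  rows <- matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8), 3, byrow = TRUE)
  state_w <- c(0.1, 0.25, 0.35, 0.3)
  part_w <- as.vector(tapply(state_w, part$index_of, sum))
  mod <- pmm(ab, model_spec(2), part, rows, part_weights = part_w)
  h_part <- entropy_closed_form(mod, D = 2)$value
  srows <- rows[part$index_of, ]
  h_state <- -sum(state_w * rowSums(ifelse(srows > 0,
                                           srows * log2(srows), 0)))
  expect_equal(h_part, h_state, tolerance = 1e-12)

  expect_error(entropy_closed_form(
    pmm(ab, model_spec(2), part, rows), D = 2), "no part weights")
})

test_that("the minimum codeword rate aliases the plug-in entropy and ln ML is refinement-monotone", {
  ct <- random_count_table(31, m = 2L, o = 2L, n = 500L)
  est <- estimate_partition(ct)
  expect_identical(min_codeword_rate(ct, est), entropy_plugin(ct, est)$value)

  # refining a partition never decreases the log pseudo-likelihood
  for (seed in 41:44) {
    ct <- random_count_table(seed, m = 2L, o = 2L, n = 300L)
    st <- ct$states
    coarse <- partition(c(1, 1, 2, 2), st)
    fine <- partition(1:4, st)
    expect_gte(log_pseudo_likelihood(aggregate_counts(ct, fine)),
               log_pseudo_likelihood(aggregate_counts(ct, coarse)) - 1e-10)
  }
})
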