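# Transition matrices, the randomized chi-square syntax test, and the
# group-level paired transition tests.

test_that("observed transitions match enumeration and are row-stochastic", {
  O <- observed_transitions(segment_runs(ms_labels(
    rep.int(c(1L, 2L, 1L, 2L, 1L), rep(3, 5)), 100, 2)), 2)
  expect_equal(O[1, 2], 1)
  expect_equal(O[2, 1], 1)
  O3 <- observed_transitions(segment_runs(ms_labels(
    rep.int(c(1L, 2L, 3L, 1L, 2L, 3L), rep(2, 6)), 100, 3)), 3)
  expect_equal(O3[1, 2], 1); expect_equal(O3[2, 3], 1); expect_equal(O3[3, 1], 1)
  set.seed(3)
  lab <- sample_label_sequence(ground_truth_config(), 5000, seed = 3)
  Or <- observed_transitions(segment_runs(lab), 4)
  expect_equal(unname(rowSums(Or)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(diag(Or) == 0))
})

test_that("expected transitions follow the label-share closed form", {
  lab <- rep.int(rep(1:4, 25), rep(2, 100))
  E <- expected_transitions(segment_runs(ms_labels(lab, 100, 4)), 4)
  expect_equal(E[1, 2], 1 / 3, tolerance = 1e-12)
  expect_true(all(abs(E[row(E) != col(E)] - 1 / 3) < 1e-12))
  # q = (0.5, 0.25, 0.25): expected(2 -> 1) = 0.5 / 0.75
  lab2 <- rep.int(c(1L, 2L, 1L, 3L), c(1, 1, 1, 1))
  runs2 <- segment_runs(ms_labels(lab2, 100, 3))
  E2 <- expected_transitions(runs2, 3)
  expect_equal(E2[2, 1], 2 / 3, tolerance = 1e-12)
  expect_equal(unname(rowSums(E2)), rep(1, 3), tolerance = 1e-12)
})

test_that("a strictly cyclic syntax is detected at the permutation floor", {
  runs <- segment_runs(ms_labels(rep.int(rep(1:4, 50), rep(2, 200)), 100, 4))
  res <- syntax_chisq_test(runs, 4, n_perm = 5000, seed = 11)
  expect_lte(res$p, 0.0006)
  expect_gte(res$p, 1 / 5001)
})

test_that("the add-one p-value never reaches zero and respects its floor", {
  set.seed(5)
  lab <- sample(1:4, 60, replace = TRUE)
  lab <- lab[c(TRUE, diff(lab) != 0)]
  res <- syntax_chisq_test(lab, 4, n_perm = 100, seed = 2)
  expect_gte(res$p, 1 / 101)
  expect_lte(res$p, 1)
})

test_that("degenerate syntax inputs error out", {
  expect_error(syntax_chisq_test(rep(1L, 20), 2, n_perm = 100, seed = 1),
               "single-label")
  expect_error(syntax_chisq_test(c(1L, 2L), 2, n_perm = 100, seed = 1),
               "10 runs")
  expect_error(syntax_chisq_test(c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
                                 2, n_perm = 10, seed = 1), "n_perm")
})

test_that("null shuffles preserve the label multiset and avoid repeats", {
  set.seed(19)
  for (i in 1:20) {
    lab <- sample(1:4, 80, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    x <- neoms:::shuffle_no_adjacent(lab)
    expect_identical(sort(x), sort(lab))
    if (max(tabulate(lab, 4)) <= (length(lab) + 1) %/% 2) {
      expect_true(all(x[-1] != x[-length(x)]))
    }
  }
})

test_that("transition tests are permutation-equivariant under relabelling", {
  set.seed(8)
  lab <- sample_label_sequence(ground_truth_config(), 20000, seed = 8)
  runs <- segment_runs(lab)
  perm <- c(3L, 1L, 4L, 2L)
  runs2 <- runs
  runs2$label <- perm[runs$label]
  O1 <- observed_transitions(runs, 4)
  O2 <- observed_transitions(runs2, 4)
  expect_equal(O2[perm, perm], O1, ignore_attr = TRUE)
  E1 <- expected_transitions(runs, 4)
  E2 <- expected_transitions(runs2, 4)
  expect_equal(E2[perm, perm], E1, ignore_attr = TRUE)
})

test_that("group transition test flags a planted transition and only it", {
  k <- 4
  P <- matrix(1 / 3, k, k); diag(P) <- 0
  P[1, ] <- c(0, 0.1, 0.8, 0.1)   # boost 1 -> 3
  detected <- 0L
  for (seed in 1:10) {
    stats <- lapply(1:8, function(e) {
      cfg <- ground_truth_config(transition_matrix = P)
      lab <- sample_label_sequence(cfg, 30000, seed = 100 * seed + e)
      runs <- segment_runs(lab)
      list(observed = observed_transitions(runs, k),
           expected = expected_transitions(runs, k))
    })
    res <- transition_group_test(stats)
    hit <- res[res$from == 1 & res$to == 3, ]
    if (hit$sig == "strong" && hit$direction == "more") detected <- detected + 1L
  }
  expect_gte(detected, 9L)
})

test_that("a null fixture with observed == expected yields no signal", {
  O <- matrix(1 / 3, 4, 4); diag(O) <- 0
  stats <- replicate(5, list(observed = O, expected = O), simplify = FALSE)
  res <- transition_group_test(stats)
  expect_true(all(res$degenerate))
  expect_true(all(res$sig == "ns"))
})

test_that("BH adjustment agrees with the step-up definition", {
  set.seed(33)
  p <- runif(12)^2
  stats <- lapply(1:5, function(e) {
    O <- matrix(runif(16), 4, 4); diag(O) <- 0
    E <- matrix(runif(16), 4, 4); diag(E) <- 0
    list(observed = O, expected = E)
  })
  res <- transition_group_test(stats)
  expect_equal(res$p_fdr, oracle_bh(res$p), tolerance = 1e-12)
})
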