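test_that("iou_score reproduces the worked matching example", {
  res <- iou_score(pred = c(1, 1, 1, 2, 2, 2), truth = c(1, 1, 1, 1, 2, 2))
  expect_equal(res$iou, (3 / 4 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(sort(res$per_domain$iou), sort(c(3 / 4, 2 / 3)))
})

test_that("iou_score boundary cases: identity, empty prediction", {
  expect_equal(iou_score(c(1, 1, 1, 2, 2), c(1, 1, 1, 2, 2))$iou, 1)
  expect_equal(iou_score(rep(0, 5), c(1, 1, 1, 2, 2))$iou, 0)
  expect_equal(iou_score(rep(0, 4), rep(0, 4))$iou, 1)
  expect_error(iou_score(1:3, 1:4), "same length")
})

test_that("iou_score is invariant to domain label permutations", {
  set.seed(29)
  for (rep in 1:25) {
    truth <- random_assignment(n_domains = sample(2:4, 1))
    pred <- random_assignment(n_domains = sample(2:4, 1))
    L <- min(length(pred), length(truth))
    pred <- pred[seq_len(L)]; truth <- truth[seq_len(L)]
    base <- iou_score(pred, truth)$iou
    perm <- sample(max(pred))
    pred2 <- ifelse(pred == 0, 0, perm[pmax(pred, 1)])
    expect_equal(iou_score(pred2, truth)$iou, base)
    expect_gte(base, 0); expect_lte(base, 1)
  }
})

test_that("the matching is optimal, not greedy", {
  # intersection matrix [[5, 4], [4, 0]]: greedy-by-largest pairs ref 1
  # with pred 1 for a total of 5; the optimal matching crosses over for 8
  truth <- c(rep(1, 9), rep(2, 4))
  pred <- c(rep(1, 5), rep(2, 4), rep(1, 4))
  res <- iou_score(pred, truth)
  expect_equal(sum(res$per_domain$intersection), 8L)
  expect_equal(res$per_domain$pred, c(2L, 1L))
})

test_that("domain_correct_fraction pools reference domains across chains", {
  pairs <- list(
    list(pred = c(1, 1, 1, 2, 2), truth = c(1, 1, 1, 2, 2)),
    list(pred = c(1, 1, 1, 2, 2, 2), truth = c(1, 1, 1, 1, 2, 2)))
  expect_equal(domain_correct_fraction(pairs), 0.5)
  expect_equal(domain_correct_fraction(pairs[[1]]), 1)
  expect_equal(domain_correct_fraction(pairs, threshold = 0), 1)
  expect_error(domain_correct_fraction(list()), "empty")
})

test_that("boundary score matches the offset-3 worked case", {
  truth <- c(rep(1, 100), rep(2, 100))
  pred <- c(rep(1, 103), rep(2, 97))
  expect_equal(boundary_distance_score(pred, truth), 6 / 8)
  expect_equal(boundary_distance_score(truth, truth), 1)
  expect_equal(boundary_distance_score(rep(1, 200), truth), 0)
  # two single-domain assignments: no boundaries on either side
  expect_equal(boundary_distance_score(rep(1, 50), rep(1, 50)), 1)
})

test_that("null transitions count as boundaries", {
  truth <- c(rep(0, 10), rep(1, 30), rep(0, 10))
  pred <- c(rep(0, 12), rep(1, 26), rep(0, 12))
  s <- boundary_distance_score(pred, truth)
  expect_gt(s, 0.5)
  expect_lt(s, 1)
})

test_that("evaluate_assignment flags the fault taxonomy", {
  truth <- c(rep(1, 20), rep(2, 20))
  split_pred <- c(rep(1, 20), rep(2, 10), rep(3, 10))
  ev <- evaluate_assignment(split_pred, truth)
  expect_true(ev$fault_flags["over_split"])
  expect_false(ev$fault_flags["under_split"])
  merged <- rep(1, 40)
  ev2 <- evaluate_assignment(merged, truth)
  expect_true(ev2$fault_flags["under_split"])
  expect_true(ev2$fault_flags["missing_domain"])
  perfect <- evaluate_assignment(truth, truth)
  expect_false(any(perfect$fault_flags))
  expect_equal(perfect$iou, 1)
  expect_equal(perfect$boundary_score, 1)
})
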