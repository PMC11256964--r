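test_that("log_likelihood matches hand-computed pair sums", {
  expect_equal(log_likelihood(c(1, 1, 1), matrix(0.9, 3, 3)), 3 * log(0.9))
  expect_equal(log_likelihood(c(0, 0, 0), matrix(0.5, 3, 3)), 3 * log(0.5))
  # saturated exact match: maximal value, ~0 for small eps
  lab <- c(1, 1, 2, 2)
  ll <- log_likelihood(lab, clipped_adjacency(lab))
  expect_gt(ll, 6 * log(1 - 1e-4) - 1e-10)
  expect_lt(ll, 0)
})

test_that("delta_score agrees with hand evaluation and no-op moves", {
  soft <- matrix(c(0.5, 0.9, 0.9, 0.5), 2, 2)
  expect_equal(delta_score(c(1, 0), soft, 2, 1), log(0.9) - log(0.1))
  expect_equal(delta_score(c(1, 0), soft, 1, 1), 0)
  expect_error(delta_score(c(1, 0), soft, 2, 5), "target domain")
})

test_that("delta_score equals full log-likelihood recomputation", {
  set.seed(15)
  for (rep in 1:200) {
    L <- sample(4:12, 1)
    labels <- sample(0:3, L, replace = TRUE)
    soft <- random_soft_adjacency(L)
    j <- sample(L, 1)
    k <- sample(0:(max(labels) + 1), 1)
    moved <- labels
    moved[j] <- k
    full <- log_likelihood(moved, soft) - log_likelihood(labels, soft)
    expect_equal(delta_score(labels, soft, j, k), full, tolerance = 1e-9)
  }
})

test_that("the greedy assigner recovers exact adjacencies", {
  cases <- list(c(1, 1, 1, 2, 2, 2),
                c(1, 1, 2, 2, 1, 1),
                rep(1:6, each = 3))  # 6 domains exceed k_init via overflow
  for (labels in cases) {
    got <- assign_domains(clipped_adjacency(labels))
    expect_equal(as.integer(got), as.integer(labels))
  }
})

test_that("sub-even co-membership yields the all-null assignment", {
  soft <- matrix(0.5 - 1e-4, 4, 4)
  diag(soft) <- 0.5
  expect_equal(as.integer(assign_domains(soft)), rep(0L, 4))
  # enumeration agrees: null is the (tie-broken) global optimum
  expect_equal(as.integer(brute_force_assign(soft)), rep(0L, 4))
})

test_that("output is invariant to the number of initial columns", {
  set.seed(33)
  for (rep in 1:10) {
    soft <- random_soft_adjacency(12)
    a1 <- assign_domains(soft, assigner_config(k_init = 1))
    a4 <- assign_domains(soft, assigner_config(k_init = 4))
    a9 <- assign_domains(soft, assigner_config(k_init = 9))
    expect_identical(as.integer(a1), as.integer(a4))
    expect_identical(as.integer(a4), as.integer(a9))
  }
})

test_that("min_domain_size demotes small domains to null", {
  labels <- c(rep(1, 10), rep(2, 3), rep(3, 10))
  got <- assign_domains(clipped_adjacency(labels),
                        assigner_config(min_domain_size = 5))
  expect_equal(as.integer(got), c(rep(1L, 10), rep(0L, 3), rep(2L, 10)))
})

test_that("brute force returns the generating assignment and handles ties", {
  labels <- c(1, 1, 2, 2, 0, 2)
  expect_equal(as.integer(brute_force_assign(clipped_adjacency(labels))),
               canonicalize_assignment(labels))
  # exactly 0.5 everywhere: all labelings tie; null wins by tie-break
  soft <- matrix(0.5, 5, 5)
  expect_equal(as.integer(brute_force_assign(soft)), rep(0L, 5))
  expect_error(brute_force_assign(random_soft_adjacency(11)), "L > 10")
})

test_that("greedy never beats the exhaustive oracle and usually ties it", {
  set.seed(21)
  n_equal <- 0
  for (rep in 1:40) {
    soft <- random_soft_adjacency(6)
    greedy <- assign_domains(soft)
    oracle <- brute_force_assign(soft, max_domains = 4)
    lg <- log_likelihood(greedy, soft)
    lo <- log_likelihood(oracle, soft)
    expect_lte(lg, lo + 1e-9)
    if (abs(lg - lo) <= 1e-9) n_equal <- n_equal + 1
  }
  expect_gte(n_equal / 40, 0.8)
})

test_that("invalid soft adjacencies are rejected", {
  bad <- matrix(runif(16), 4, 4)  # asymmetric
  expect_error(assign_domains(bad), "symmetric")
  neg <- matrix(-0.1, 2, 2)
  expect_error(assign_domains(neg), "0, 1")
})
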