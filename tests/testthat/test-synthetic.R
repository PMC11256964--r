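test_that("generation is deterministic and sizes follow the plan", {
  spec <- synthetic_spec(n_domains = 2, domain_sizes = c(40, 40),
                         null_tail_prob = 0)
  g1 <- generate_chain(spec, seed = 7)
  g2 <- generate_chain(spec, seed = 7)
  expect_identical(g1, g2)
  # 80 domain residues plus one linker of 3..8
  expect_gte(length(g1$chain), 80)
  expect_lte(length(g1$chain), 88)
  expect_equal(sum(g1$assignment == 1), 40)
  expect_equal(sum(g1$assignment == 2), 40)
  expect_equal(length(g1$ss$labels), length(g1$chain))
})

test_that("intra-domain distances stay below inter-domain distances", {
  set.seed(55)
  ok <- 0
  n_chains <- 40
  for (r in seq_len(n_chains)) {
    g <- generate_chain(synthetic_spec(n_domains = sample(2:3, 1)))
    D <- distance_matrix(g$chain)
    a <- g$assignment
    nz <- outer(a != 0, a != 0, "&") & upper.tri(D)
    same <- outer(a, a, "==") & nz
    diff <- outer(a, a, "!=") & nz
    if (mean(D[same]) < mean(D[diff])) ok <- ok + 1
  }
  expect_gte(ok / n_chains, 0.99)
})

test_that("a forced null tail appends unassigned coil residues", {
  g <- generate_chain(synthetic_spec(n_domains = 1, domain_sizes = 30,
                                     null_tail_prob = 1), seed = 3)
  L <- length(g$chain)
  expect_gt(L, 30)
  expect_true(all(g$assignment[31:L] == 0))
  expect_true(all(g$ss$labels[31:L] == "C"))
})

test_that("discontinuous domains revisit their centroid", {
  found <- FALSE
  for (s in 1:30) {
    g <- generate_chain(synthetic_spec(n_domains = 2,
                                       domain_sizes = c(20, 20),
                                       discontinuous_prob = 1,
                                       null_tail_prob = 0), seed = s)
    r <- rle(g$assignment[g$assignment != 0])
    if (length(r$values) > 2) {
      found <- TRUE
      # the split domain's two segments stay spatially compact
      idx <- which(g$assignment == 1)
      D <- distance_matrix(g$chain)
      expect_lt(max(D[idx, idx]), 2.5 * 8)
      break
    }
  }
  expect_true(found)
})

test_that("corrupt_adjacency interpolates between truth and noise", {
  labels <- c(rep(1, 10), rep(2, 10))
  A <- assignment_to_adjacency(labels)
  clean <- corrupt_adjacency(A, 0, seed = 1)
  expect_equal(clean, domseg:::clip_prob(A, 1e-4))
  expect_equal(as.integer(assign_domains(clean)), as.integer(labels))
  noisy <- corrupt_adjacency(A, 1, seed = 1)
  expect_identical(noisy, t(noisy))
  expect_gt(mean(abs(noisy - domseg:::clip_prob(A, 1e-4))), 0.1)
})

test_that("recovery degrades monotonically with noise on average", {
  set.seed(91)
  levels <- c(0, 0.2, 0.4, 0.6)
  mean_iou <- vapply(levels, function(nl) {
    mean(vapply(1:20, function(r) {
      labels <- random_assignment(n_domains = sample(2:3, 1),
                                  size_range = c(8, 20))
      soft <- corrupt_adjacency(assignment_to_adjacency(labels), nl)
      iou_score(assign_domains(soft), labels)$iou
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_iou) <= 0))
  expect_equal(mean_iou[1], 1)
})

test_that("make_dataset flags classes and emits valid labels", {
  ds <- make_dataset(10, function() synthetic_spec(1, 30), seed = 2)
  expect_true(all(vapply(ds, `[[`, "", "flag") == "single"))
  mixed <- make_dataset(40, seed = 6)
  flags <- vapply(mixed, `[[`, "", "flag")
  expect_gt(mean(flags == "single"), 0.25)
  expect_lt(mean(flags == "single"), 0.75)
  for (item in mixed[1:5]) {
    back <- adjacency_to_assignment(item$label)
    expect_identical(back, canonicalize_assignment(item$assignment))
    expect_equal(dim(item$features)[1:2], dim(item$label))
  }
})

test_that("spec validation enforces the separation premise", {
  expect_error(synthetic_spec(2, centroid_separation = 10, intra_spread = 8),
               "separation")
  expect_error(synthetic_spec(2, domain_sizes = c(4, 40)), "domain_sizes")
})
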