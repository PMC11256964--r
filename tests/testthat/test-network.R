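tiny_cfg <- network_config(n_blocks = 2, n_filters = 6,
                           dilation_cycle = c(1, 2))

test_that("the default architecture matches its stated size", {
  cfg <- network_config()
  expect_equal(cfg$n_blocks, 31L)
  expect_equal(cfg$n_filters, 32L)
  model <- build_model(cfg, seed = 1)
  blocks <- grep("^blk", names(model$params), value = TRUE)
  expect_equal(length(unique(substr(blocks, 1, 5))), 31)
  expect_equal(nrow(model$params$blk01_W1), 32)
})

test_that("one weight set serves inputs of any length", {
  model <- build_model(tiny_cfg, seed = 5)
  for (L in c(7, 16, 64, 200)) {
    x <- array(rnorm(L * L * 5), dim = c(L, L, 5))
    soft <- predict_soft_adjacency(model, x)
    expect_equal(dim(soft), c(L, L))
    expect_true(all(soft > 0 & soft < 1))
    # symmetry is exact, not approximate
    expect_identical(soft, t(soft))
  }
})

test_that("predictions are bitwise invariant to the coordinate frame", {
  set.seed(13)
  g <- generate_chain(synthetic_spec(n_domains = 2,
                                     domain_sizes = c(15, 15)), seed = 6)
  model <- build_model(tiny_cfg, seed = 5)
  p0 <- predict_soft_adjacency(model, featurize(g$chain, g$ss))
  for (reflect in c(FALSE, TRUE)) {
    moved <- protein_chain(random_rigid_transform(g$chain$ca_coords,
                                                  reflect = reflect))
    p1 <- predict_soft_adjacency(model, featurize(moved, g$ss))
    expect_lt(max(abs(p0 - p1)), 1e-9)
  }
})

test_that("bce_loss reproduces its closed forms", {
  L <- 6
  target <- assignment_to_adjacency(rep(1:2, each = 3))
  expect_equal(bce_loss(matrix(0.5, L, L), target), log(2),
               tolerance = 1e-12)
  # single pair, p = 0.9 against a = 1
  t2 <- assignment_to_adjacency(c(1, 1))
  expect_equal(bce_loss(matrix(0.9, 2, 2), t2), -log(0.9),
               tolerance = 1e-12)
  # perfect clipped prediction: loss ~ eps
  lab <- c(1, 1, 2, 2)
  expect_equal(bce_loss(clipped_adjacency(lab), assignment_to_adjacency(lab)),
               -log(1 - 1e-4), tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("an untrained model scores ~ln 2 against random labels", {
  set.seed(23)
  model <- build_model(tiny_cfg, seed = 8)
  losses <- replicate(20, {
    L <- sample(10:30, 1)
    x <- array(rnorm(L * L * 5), dim = c(L, L, 5))
    labels <- sample(0:2, L, replace = TRUE)
    bce_loss(predict_soft_adjacency(model, x),
             assignment_to_adjacency(labels))
  })
  expect_equal(mean(losses), log(2), tolerance = 0.05)
})

test_that("analytic gradients match finite differences", {
  set.seed(31)
  cfg <- network_config(n_blocks = 2, n_filters = 3, dilation_cycle = c(1, 2))
  model <- build_model(cfg, seed = 2)
  L <- 6
  x <- array(rnorm(L * L * 5), dim = c(L, L, 5))
  A <- assignment_to_adjacency(c(1, 1, 1, 2, 2, 0))
  fwd <- domseg:::net_forward(model$params, x, cfg, keep_cache = TRUE)
  G <- (plogis(fwd$logits) - A)
  diag(G) <- 0
  G <- G / (L * (L - 1))
  grads <- domseg:::net_backward(model$params, cfg, fwd$cache, G)
  eps <- 1e-6
  for (nm in names(model$params)) {
    w <- model$params[[nm]]
    for (ii in sample(length(w), min(2, length(w)))) {
      p2 <- model$params
      p2[[nm]][ii] <- p2[[nm]][ii] + eps
      up <- domseg:::bce_from_logits(
        domseg:::net_forward(p2, x, cfg)$logits, A)
      p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
      dn <- domseg:::bce_from_logits(
        domseg:::net_forward(p2, x, cfg)$logits, A)
      num <- (up - dn) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and is deterministic under a seed", {
  sampler <- function() synthetic_spec(
    n_domains = if (runif(1) < 0.5) 1 else 2, size_range = c(10, 16),
    centroid_separation = 25, intra_spread = 8)
  ds <- make_dataset(16, spec_sampler = sampler, seed = 71)
  cfg <- training_config(epochs = 3, seed = 12)
  m1 <- train_segmenter(NULL, ds, cfg, tiny_cfg)
  h <- m1$history
  expect_equal(nrow(h), 3 * 16)
  expect_lt(mean(h$loss[h$epoch == 3]), mean(h$loss[h$epoch == 1]))
  m2 <- train_segmenter(NULL, ds, cfg, tiny_cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("degenerate class sampling never draws the other class", {
  # the single-domain item has features/label of mismatched size, so
  # sampling it would error; with p_multi = 1 it must never be drawn
  good <- make_dataset(2, function() synthetic_spec(2, c(10, 10)), seed = 5)
  trap <- good[[1]]
  trap$flag <- "single"
  trap$label <- trap$label[1:5, 1:5]
  ds <- list(good[[1]], good[[2]], trap)
  ds[[1]]$flag <- "multi"
  ds[[2]]$flag <- "multi"
  expect_no_error(train_segmenter(
    NULL, ds, training_config(p_multi = 1, p_single = 0, epochs = 1,
                              seed = 3), tiny_cfg))
  expect_error(training_config(p_multi = 0.5, p_single = 0.2), "equal 1")
})

test_that("checkpoints round-trip through save_model/load_model", {
  model <- build_model(tiny_cfg, seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$params, model$params)
  saveRDS(list(1), path)
  expect_error(load_model(path), "not a domain_cnn")
})
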